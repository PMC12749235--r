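#' Character maps: bijections between fixed-length bit strings and characters
#'
#' A character map assigns one character to every bit string of length
#' `bits_per_char`, so that encoding and decoding are exact inverses. The
#' integer code of a character is the value of its bit string read as binary
#' (most significant bit first).
#'
#' @param chars character vector of length `2^bits_per_char`, in code order
#'   (element 1 is code 0). Entries may be `NA` to leave a code unassigned;
#'   decoding an unassigned code yields an invalid readout.
#' @param bits_per_char number of bits per character; inferred from
#'   `length(chars)` when omitted.
#' @return an object of class `character_map` with fields `bits_per_char`
#'   and `chars`.
#' @examples
#' cm <- character_map(c("0", "1", "2", "3"))
#' char_to_code(cm, "2")
#' code_to_char(cm, 2L)
#' @export
character_map <- function(chars, bits_per_char = NULL) {
  chars <- as.character(chars)
  if (is.null(bits_per_char)) {
    bits_per_char <- as.integer(round(log2(length(chars))))
  }
  if (length(chars) != 2^bits_per_char) {
    stop("`chars` must have exactly 2^bits_per_char = ", 2^bits_per_char,
         " entries, got ", length(chars))
  }
  dup <- duplicated(chars[!is.na(chars)])
  if (any(dup)) {
    stop("character map is not injective: duplicated character(s) ",
         paste(unique(chars[!is.na(chars)][dup]), collapse = ", "))
  }
  structure(list(bits_per_char = as.integer(bits_per_char), chars = chars),
            class = "character_map")
}

#' @export
print.character_map <- function(x, ...) {
  cat("<character_map> ", x$bits_per_char, " bits, ",
      sum(!is.na(x$chars)), "/", length(x$chars), " codes assigned\n", sep = "")
  invisible(x)
}

#' Look up the integer code of a character
#'
#' @param cmap a [character_map()]
#' @param char single character present in the map
#' @return integer code in `[0, 2^bits_per_char - 1]`
#' @export
char_to_code <- function(cmap, char) {
  stopifnot(inherits(cmap, "character_map"))
  i <- match(char, cmap$chars)
  if (is.na(i)) stop("character ", dQuote(char), " is not in the map")
  i - 1L
}

#' Look up the character assigned to an integer code
#'
#' @param cmap a [character_map()]
#' @param code integer code
#' @return the character, or `NA_character_` if the code is unassigned
#' @export
code_to_char <- function(cmap, code) {
  stopifnot(inherits(cmap, "character_map"))
  if (code < 0L || code >= length(cmap$chars)) {
    stop("code ", code, " outside [0, ", length(cmap$chars) - 1L, "]")
  }
  cmap$chars[[code + 1L]]
}

#' Built-in character maps
#'
#' `default_map_6bit()` covers a 64-symbol alphabet: code 0 is `"@"`,
#' codes 1--26 are `A`--`Z` (so `A` has the low code 000001), codes 27--36
#' are the digits `0`--`9`, and the remaining 27 codes are punctuation.
#' With this layout a dropped bit in `A` (000001) reads as `@` and a dropped
#' bit in `S` (010011) can read as `Q` (010001) -- the characteristic false
#' readouts of noisy high-density patterns.
#'
#' `default_map_3bit()` is the 8-symbol demo alphabet used with the 12-site
#' rectangle (`{@, A, F, N, S, U, E, T}`), and `digit_map(bits)` maps codes
#' to digits (hexadecimal characters beyond 9) for number-encoding rules.
#'
#' @return a [character_map()]
#' @export
default_map_6bit <- function() {
  punct <- c(" ", ".", ",", "!", "?", ":", ";", "'", "\"", "-", "_",
             "(", ")", "[", "]", "{", "}", "/", "\\", "+", "=", "*",
             "&", "%", "$", "#", "~")
  character_map(c("@", LETTERS, as.character(0:9), punct))
}

#' @rdname default_map_6bit
#' @export
default_map_3bit <- function() {
  character_map(c("@", "A", "F", "N", "S", "U", "E", "T"))
}

#' @rdname default_map_6bit
#' @param bits bits per character (2--4)
#' @export
digit_map <- function(bits = 4L) {
  stopifnot(bits >= 1, bits <= 4)
  character_map(c(as.character(0:9), LETTERS[1:6])[seq_len(2^bits)])
}

## integer <-> bit-vector helpers (MSB first); exact for values < 2^31
int_to_bits <- function(value, width) {
  stopifnot(value >= 0, value < 2^width)
  as.integer(bitwAnd(bitwShiftR(as.integer(value), (width - 1L):0L), 1L))
}

bits_to_int <- function(bits) {
  v <- 0L
  for (b in bits) v <- v * 2L + as.integer(b)
  v
}
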