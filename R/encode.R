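#' Encode a text message into per-origami bit patterns
#'
#' Each character of `text` becomes one origami pattern: the character's
#' code fills the character-bit field and the 1-based position of the
#' character in the text fills the position-bit field (so position 1 is
#' `...001`). The occupied sites of a pattern are the filled orientation
#' markers plus every site of the redundancy group of every 1-bit.
#'
#' @param text character scalar; every character must be in `cmap`
#' @param rule a [pattern_rule()]
#' @param cmap a [character_map()] with `bits_per_char == rule$char_bit_count`
#' @return list of `bit_pattern` objects, one per character, each with
#'   fields `occupied` (logical per site), `character`, `position`
#' @examples
#' pats <- encode_message("NSF", rule_rro12(), default_map_3bit())
#' sum(pats[[1]]$occupied)
#' @export
encode_message <- function(text, rule, cmap) {
  stopifnot(inherits(rule, "pattern_rule"), inherits(cmap, "character_map"))
  if (cmap$bits_per_char != rule$char_bit_count) {
    stop("map has ", cmap$bits_per_char, " bits per character but the rule ",
         "allocates ", rule$char_bit_count)
  }
  chars <- strsplit(text, "")[[1]]
  max_len <- 2^rule$pos_bit_count - 1
  if (length(chars) > max_len) {
    stop("text of length ", length(chars), " does not fit the ",
         rule$pos_bit_count, "-bit position field (max ", max_len, ")")
  }
  lapply(seq_along(chars), function(i) {
    code <- char_to_code(cmap, chars[[i]])
    bit_pattern(rule, chars[[i]], i, code)
  })
}

bit_pattern <- function(rule, character, position, code = NULL) {
  if (is.null(code)) code <- NA_integer_
  bits <- c(int_to_bits(code, rule$char_bit_count),
            int_to_bits(position, rule$pos_bit_count))
  occupied <- rep(FALSE, n_sites(rule))
  occupied[filled_marker_sites(rule)] <- TRUE
  for (j in which(bits == 1L)) occupied[rule$redundancy[[j]]] <- TRUE
  structure(list(occupied = occupied, character = character,
                 position = as.integer(position), logical_bits = bits),
            class = "bit_pattern")
}

#' A pattern occupying every site of a geometry
#'
#' Used for detection-efficiency runs, where all docking sites carry an
#' information strand and the per-site detection probability is estimated
#' from how often each site shows up across particles.
#'
#' @param rule a [pattern_rule()]
#' @return a `bit_pattern` with all sites occupied
#' @export
full_pattern <- function(rule) {
  structure(list(occupied = rep(TRUE, n_sites(rule)),
                 character = NA_character_, position = NA_integer_,
                 logical_bits = rep(1L, rule$char_bit_count + rule$pos_bit_count)),
            class = "bit_pattern")
}

#' Decode a logical bit string into (character, position)
#'
#' The inverse of [encode_message()] on clean input: the first
#' `char_bit_count` bits (MSB first) are the character code, the remaining
#' `pos_bit_count` bits the 1-based position. A code with no assigned
#' character, or position 0, is flagged invalid rather than raising an
#' error -- an invalid readout counts as wrong, not fatal.
#'
#' @param bits integer/logical vector of logical bits (post-redundancy
#'   collapse), length `char_bit_count + pos_bit_count`
#' @param rule a [pattern_rule()]
#' @param cmap a [character_map()]
#' @return list with `character`, `position`, `valid`
#' @export
decode_bits <- function(bits, rule, cmap) {
  stopifnot(length(bits) == rule$char_bit_count + rule$pos_bit_count)
  bits <- as.integer(bits)
  code <- bits_to_int(bits[seq_len(rule$char_bit_count)])
  pos <- bits_to_int(bits[rule$char_bit_count + seq_len(rule$pos_bit_count)])
  char <- code_to_char(cmap, code)
  list(character = char, position = as.integer(pos),
       valid = !is.na(char) && pos >= 1L)
}

#' Key-size and capacity arithmetic
#'
#' @description
#' `docking_key_bits(length, alphabet)` is the key size in bits of a docking
#' sequence of `length` letters over an `alphabet`-letter alphabet:
#' `length * log2(alphabet)` (an 8-nt sequence over 4 nucleotides is a
#' 16-bit key).
#'
#' `capacity(bits)` is the exact number of symbols `2^bits` encodable with
#' `bits` bits, computed in exact integer arithmetic (no floating point)
#' for `bits <= 300`.
#'
#' `z_capacity_estimate(height, z_sep, inplane_sites)` estimates the bit
#' capacity of an idealized rigid 3D origami: `floor(height / z_sep)` site
#' levels along z times `inplane_sites` sites per level.
#'
#' @param length docking sequence length (nt), `>= 0`
#' @param alphabet alphabet size, `>= 2`
#' @return `docking_key_bits`: bits (numeric); `capacity`: exact integer
#'   count (a `bigz`-free base-R exact integer held as numeric when it fits
#'   2^53, otherwise a digit string); `z_capacity_estimate`: bits (integer)
#' @examples
#' docking_key_bits(8, 4)    # 16
#' capacity(28)              # 268435456
#' z_capacity_estimate(75, 5, 20) # 300
#' @export
docking_key_bits <- function(length, alphabet) {
  stopifnot(length >= 0, alphabet >= 2)
  length * log2(alphabet)
}

#' @rdname docking_key_bits
#' @param bits bit count, `0 <= bits <= 300`
#' @export
capacity <- function(bits) {
  stopifnot(bits >= 0, bits <= 300, bits == round(bits))
  if (bits <= 52) return(2^bits) # exact in double
  ## exact doubling in base-1e9 limbs, least significant first
  limbs <- 1
  for (i in seq_len(bits)) {
    limbs <- limbs * 2
    carry <- 0
    for (j in seq_along(limbs)) {
      limbs[j] <- limbs[j] + carry
      carry <- limbs[j] %/% 1e9
      limbs[j] <- limbs[j] %% 1e9
    }
    if (carry > 0) limbs <- c(limbs, carry)
  }
  digits <- c(format(limbs[length(limbs)], scientific = FALSE),
              sprintf("%09d", rev(limbs[-length(limbs)])))
  paste(digits, collapse = "")
}

#' @rdname docking_key_bits
#' @param height structure height along z (nm), `> 0`
#' @param z_sep axial site separation (nm), `> 0`
#' @param inplane_sites sites per z level, `> 0`
#' @export
z_capacity_estimate <- function(height, z_sep, inplane_sites) {
  stopifnot(height > 0, z_sep > 0, inplane_sites > 0)
  levels <- floor(height / z_sep)
  as.integer(levels * inplane_sites)
}
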