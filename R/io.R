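LOC_HEADER <- "# paintcrypt-localizations v1 units=nm"
MANDATORY_COLS <- c("particle_id", "frame", "x", "y", "z", "sigma_xy", "sigma_z")

#' Read and write localization tables
#'
#' The wire format is CSV with a leading metadata line declaring the format
#' and the coordinate units (`nm`). All mandatory columns
#' (`particle_id`, `frame`, `x`, `y`, `z`, `sigma_xy`, `sigma_z`) are
#' round-tripped losslessly and unknown extra columns are preserved. 2D
#' tables carry `z = 0` rather than omitting the column, so one schema
#' serves both geometries. A file without the units metadata line is
#' refused rather than silently assumed to be in nm.
#'
#' @param table localization data.frame
#' @param path file path
#' @return `read_localizations`: the data.frame; `write_localizations`:
#'   `path`, invisibly
#' @export
write_localizations <- function(table, path) {
  missing_cols <- setdiff(MANDATORY_COLS, names(table))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w")
  writeLines(LOC_HEADER, con)
  close(con)
  data.table::fwrite(table, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("units=nm", first, fixed = TRUE)) {
    stop("no unit metadata in ", path,
         ": expected a first line declaring units=nm")
  }
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  missing_cols <- setdiff(MANDATORY_COLS, names(dt))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Import a generic SMLM localization CSV
#'
#' For externally produced tables (e.g. exported from SMLM processing
#' software): maps the caller's column names onto the package schema and
#' converts units to nm. The unit scale must be stated explicitly.
#'
#' @param path CSV file with a header row
#' @param columns named character vector mapping package columns to file
#'   columns, e.g. `c(particle_id = "group", x = "x", y = "y")`; `frame`,
#'   `z`, `sigma_xy`, `sigma_z` default to 0 when unmapped
#' @param unit_nm size of one coordinate unit in nm (e.g. 130 for
#'   130-nm camera pixels); no default on purpose
#' @return localization data.frame in package schema
#' @export
read_smlm_csv <- function(path, columns, unit_nm) {
  if (missing(unit_nm)) stop("state the coordinate unit explicitly via unit_nm")
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("particle_id", "x", "y")
  if (!all(need %in% names(columns))) {
    stop("columns must map at least: ", paste(need, collapse = ", "))
  }
  absent <- setdiff(unname(columns), names(dt))
  if (length(absent)) {
    stop("file has no column(s): ", paste(absent, collapse = ", "))
  }
  get <- function(col, default) {
    if (col %in% names(columns)) dt[[columns[[col]]]]
    else rep(default, nrow(dt))
  }
  scale_cols <- function(v) v * unit_nm
  data.frame(particle_id = as.integer(get("particle_id", NA)),
             frame = as.integer(get("frame", 0L)),
             x = scale_cols(get("x", NA)),
             y = scale_cols(get("y", NA)),
             z = scale_cols(get("z", 0)),
             sigma_xy = scale_cols(get("sigma_xy", 0)),
             sigma_z = scale_cols(get("sigma_z", 0)))
}

#' Serialize and restore pattern rules and character maps
#'
#' Rules and maps are the decryption "key 1" and travel in a single
#' human-readable YAML config; round trips are exact.
#'
#' @param rule a [pattern_rule()]
#' @param cmap a [character_map()]
#' @param path YAML file
#' @return writers return `path` invisibly; readers the restored object
#' @export
write_rule_config <- function(rule, path, cmap = NULL) {
  obj <- list(geometry_id = rule$geometry_id,
              char_bit_count = rule$char_bit_count,
              pos_bit_count = rule$pos_bit_count,
              pitch = rule$pitch,
              sites = lapply(seq_len(n_sites(rule)), function(i) {
                s <- rule$sites[i, ]
                list(x = s$x, y = s$y, z = s$z, role = s$role,
                     logical_bit = if (is.na(s$logical_bit)) NULL
                                   else as.integer(s$logical_bit))
              }))
  if (!is.null(cmap)) {
    obj$character_map <- list(bits_per_char = cmap$bits_per_char,
                              chars = as.list(cmap$chars))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_rule_config
#' @export
read_rule_config <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("geometry_id", "char_bit_count", "pos_bit_count", "pitch", "sites")
  absent <- setdiff(need, names(obj))
  if (length(absent)) {
    stop("rule config ", path, " lacks field(s): ",
         paste(absent, collapse = ", "))
  }
  sites <- do.call(rbind, lapply(obj$sites, function(s) {
    data.frame(x = s$x, y = s$y, z = s$z, role = s$role,
               logical_bit = if (is.null(s$logical_bit)) NA_integer_
                             else as.integer(s$logical_bit))
  }))
  rule <- pattern_rule(obj$geometry_id, sites, obj$char_bit_count,
                       obj$pos_bit_count, obj$pitch)
  cmap <- NULL
  if (!is.null(obj$character_map)) {
    chars <- vapply(obj$character_map$chars,
                    function(x) if (is.null(x)) NA_character_ else x,
                    character(1))
    cmap <- character_map(chars, obj$character_map$bits_per_char)
  }
  list(rule = rule, cmap = cmap)
}

#' Run configuration with a provenance hash
#'
#' Bundles the rule id, generator, elbow/filter/alignment configurations
#' and master seed of one run; `config_hash()` is a stable 32-bit FNV-1a
#' hash of the canonical JSON serialization, embedded in every output so
#' that runs with equal hashes are bit-identical.
#'
#' @param rule_id geometry id of the rule in force
#' @param seed master seed
#' @param generator,elbow,filter,alignment the stage configurations
#' @param n_runs readout repeat count
#' @return object of class `run_config`
#' @export
run_config <- function(rule_id, seed, generator = generator_config(),
                       elbow = NULL, filter = filter_config(),
                       alignment = alignment_config(), n_runs = 3L) {
  structure(list(rule_id = rule_id, seed = as.integer(seed),
                 generator = generator, elbow = elbow, filter = filter,
                 alignment = alignment, n_runs = as.integer(n_runs)),
            class = "run_config")
}

#' @rdname run_config
#' @param x any serializable object (usually a `run_config`)
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(unclass_recursive(x), digits = NA, auto_unbox = TRUE)
  fnv1a32(as.character(json))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

## 32-bit FNV-1a over the UTF-8 bytes, returned as 8 hex digits; all
## arithmetic in doubles (exact below 2^53) since the state exceeds the
## signed 32-bit range of R's bitwXor
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261 # 0x811c9dc5
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
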