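#' Pattern-encryption rules
#'
#' A pattern rule ("key 1" of the protocol) fixes, for one origami geometry,
#' the position of every docking site and the semantic role of each:
#' `marker_filled` (always-occupied orientation marker), `marker_empty`
#' (deliberately empty site), `char_bit` (character information) or
#' `pos_bit` (position information). Each logical bit owns a non-empty,
#' disjoint set of sites (its redundancy group); the physical pattern for a
#' 1-bit occupies every site of the group, and readout ORs the group back
#' into the logical bit.
#'
#' Site coordinates are template-local nanometres: origin at the layout
#' centroid, `z = 0` for the planar geometries.
#'
#' @param geometry_id template name
#' @param sites data.frame with columns `x`, `y`, `z` (nm), `role`
#'   (one of `"marker_filled"`, `"marker_empty"`, `"char_bit"`, `"pos_bit"`)
#'   and `logical_bit` (integer index of the logical bit an information site
#'   belongs to, `NA` for markers)
#' @param char_bit_count,pos_bit_count number of character / position bits
#' @param pitch design pitch of the geometry in nm (minimum intended
#'   site-to-site distance)
#' @return an object of class `pattern_rule`
#' @seealso [rule_rro12()], [rule_rro24()], [rule_rro48()],
#'   [rule_cuboctahedron()], [rule_tetrapod_dimer()], [build_template()]
#' @export
pattern_rule <- function(geometry_id, sites, char_bit_count, pos_bit_count,
                         pitch) {
  roles <- c("marker_filled", "marker_empty", "char_bit", "pos_bit")
  stopifnot(is.data.frame(sites),
            all(c("x", "y", "z", "role", "logical_bit") %in% names(sites)))
  if (!all(sites$role %in% roles)) {
    stop("unknown site role(s): ",
         paste(setdiff(unique(sites$role), roles), collapse = ", "))
  }
  nbits <- as.integer(char_bit_count + pos_bit_count)
  info <- sites$role %in% c("char_bit", "pos_bit")
  if (any(is.na(sites$logical_bit[info]))) {
    stop("every information site needs a logical_bit index")
  }
  if (any(!is.na(sites$logical_bit[!info]))) {
    stop("marker sites must not carry a logical_bit index")
  }
  redundancy <- lapply(seq_len(nbits), function(j) {
    which(!is.na(sites$logical_bit) & sites$logical_bit == j)
  })
  if (any(lengths(redundancy) == 0L)) {
    stop("logical bit(s) without any site: ",
         paste(which(lengths(redundancy) == 0L), collapse = ", "))
  }
  cb <- sites$role[vapply(redundancy, `[`, 1L, 1L)]
  expected <- rep(c("char_bit", "pos_bit"),
                  c(char_bit_count, pos_bit_count))
  if (!identical(cb, expected)) {
    stop("logical bits 1..", char_bit_count, " must be char bits and ",
         char_bit_count + 1L, "..", nbits, " position bits")
  }
  for (j in seq_len(nbits)) {
    if (length(unique(sites$role[redundancy[[j]]])) != 1L) {
      stop("redundancy group of bit ", j, " mixes roles")
    }
  }
  d <- stats::dist(sites[, c("x", "y", "z")])
  if (any(d < pitch - 1e-6)) {
    stop("pairwise site distance below the design pitch (", pitch, " nm)")
  }
  rule <- structure(list(geometry_id = geometry_id,
                         sites = sites,
                         char_bit_count = as.integer(char_bit_count),
                         pos_bit_count = as.integer(pos_bit_count),
                         redundancy = redundancy,
                         pitch = pitch),
                    class = "pattern_rule")
  viol <- marker_symmetry_violations(rule)
  if (length(viol)) {
    stop("filled-marker set is invariant under in-plane rotation(s) ",
         paste(round(viol, 2), collapse = ", "),
         " degrees; markers must break all layout symmetries")
  }
  rule
}

#' @export
print.pattern_rule <- function(x, ...) {
  cat("<pattern_rule> ", x$geometry_id, ": ", nrow(x$sites), " sites (",
      sum(x$sites$role == "marker_filled"), " filled markers, ",
      sum(x$sites$role == "marker_empty"), " empty markers), ",
      x$char_bit_count, "+", x$pos_bit_count,
      " logical bits, pitch ", x$pitch, " nm\n", sep = "")
  invisible(x)
}

n_sites <- function(rule) nrow(rule$sites)

is_rule_3d <- function(rule) any(abs(rule$sites$z) > 1e-9)

filled_marker_sites <- function(rule) which(rule$sites$role == "marker_filled")

empty_marker_sites <- function(rule) which(rule$sites$role == "marker_empty")

#' In-plane rotational symmetries of a site layout
#'
#' Finds the rotation angles (about the z axis through the layout centroid)
#' that map the full site set onto itself, then reports which of them also
#' map the filled-marker set onto itself. A valid rule must report none:
#' otherwise the pattern orientation is ambiguous at readout.
#'
#' @param rule a [pattern_rule()]
#' @param tol matching tolerance in nm
#' @return numeric vector of violating angles in degrees (empty when the
#'   markers break every nontrivial symmetry)
#' @export
marker_symmetry_violations <- function(rule, tol = 1e-6) {
  xy <- as.matrix(rule$sites[, c("x", "y")])
  z <- rule$sites$z
  ctr <- colMeans(xy)
  xy <- sweep(xy, 2, ctr)
  maps_onto <- function(idx, angle) {
    th <- angle * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- xy[idx, , drop = FALSE] %*% t(R)
    for (i in seq_along(idx)) {
      d2 <- (xy[idx, 1] - rot[i, 1])^2 + (xy[idx, 2] - rot[i, 2])^2 +
        (z[idx] - z[idx][i])^2
      if (min(d2) > tol^2) return(FALSE)
    }
    TRUE
  }
  all_idx <- seq_len(nrow(xy))
  cand <- sort(unique(unlist(lapply(2:12, function(m) 360 * seq_len(m - 1) / m))))
  sym <- cand[vapply(cand, function(a) maps_onto(all_idx, a), logical(1))]
  if (!length(sym)) return(numeric(0))
  marks <- filled_marker_sites(rule)
  viol <- vapply(sym, function(a) maps_onto(marks, a), logical(1))
  sort(sym[viol])
}

## centered rectangular grid, row-major (row 1 = top), y decreasing with row
grid_sites <- function(nrow_, ncol_, pitch) {
  g <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  data.frame(x = (g$col - (ncol_ + 1) / 2) * pitch,
             y = ((nrow_ + 1) / 2 - g$row) * pitch,
             z = 0)
}

grid_index <- function(row, col, ncol_) as.integer((row - 1L) * ncol_ + col)

#' Built-in pattern rules
#'
#' @description
#' The shipped geometries and their default rules:
#'
#' * `rule_rro12()`: 12-site rectangular origami (4 x 3 grid, 20 nm pitch).
#'   2 filled corner markers, 3 character bits + 3 position bits, no
#'   redundancy; the 8-symbol demo alphabet of [default_map_3bit()] fits it.
#' * `rule_rro24()`: 24-site rectangle (6 x 4 grid, 14 nm pitch); 3 filled +
#'   1 empty corner marker, 6 + 6 logical bits, no redundancy.
#' * `rule_rro48()`: 48-site rectangle (8 x 6 grid, 10 nm pitch); 12 filled
#'   markers (3 per corner, one corner's motif laid along the row so no
#'   180-degree rotation preserves the marker set), 6 character + 6 position
#'   bits each with one redundant site (24 information sites), 12 empty
#'   edge sites.
#' * `rule_cuboctahedron()`: 12 vertices of a cuboctahedron with a square
#'   face horizontal, scaled so the z separation of stacked vertices is
#'   67.5 nm; 3 filled + 2 empty markers, 4 number bits + 3 position bits.
#' * `rule_tetrapod_dimer()`: 8 arm-end sites of two tetrapods (35 nm arms,
#'   tetrahedral arm directions) joined along one arm axis; 2 filled + 1
#'   empty marker, 3 number bits + 2 position bits.
#'
#' `redundancy = FALSE` collapses every redundancy group to its first
#' (main) site, turning the redundant sites into empty markers -- the
#' "without redundancy" readout of the same physical pattern.
#' @param redundancy keep the redundant sites of `rule_rro48()`? (see above)
#' @return a [pattern_rule()]
#' @export
rule_rro12 <- function() {
  sites <- grid_sites(3L, 4L, 20)
  sites$role <- "marker_empty"
  sites$logical_bit <- NA_integer_
  ## the two top corners: far apart, so no wrong placement can match both
  ## markers while keeping the information block on the grid
  sites$role[c(grid_index(1, 1, 4), grid_index(1, 4, 4))] <- "marker_filled"
  for (j in 1:3) {
    i <- grid_index(2, j, 4)
    sites$role[i] <- "char_bit"; sites$logical_bit[i] <- j
  }
  for (j in 1:3) {
    i <- grid_index(3, j, 4)
    sites$role[i] <- "pos_bit"; sites$logical_bit[i] <- 3L + j
  }
  pattern_rule("rro12", sites, 3L, 3L, pitch = 20)
}

#' @rdname rule_rro12
#' @export
rule_rro24 <- function() {
  sites <- grid_sites(4L, 6L, 14)
  sites$role <- "marker_empty"
  sites$logical_bit <- NA_integer_
  sites$role[c(grid_index(1, 1, 6), grid_index(1, 6, 6),
               grid_index(4, 1, 6))] <- "marker_filled"
  for (j in 1:6) {
    i <- grid_index(2, j, 6)
    sites$role[i] <- "char_bit"; sites$logical_bit[i] <- j
  }
  for (j in 1:6) {
    i <- grid_index(3, j, 6)
    sites$role[i] <- "pos_bit"; sites$logical_bit[i] <- 6L + j
  }
  pattern_rule("rro24", sites, 6L, 6L, pitch = 14)
}

#' @rdname rule_rro12
#' @export
rule_rro48 <- function(redundancy = TRUE) {
  sites <- grid_sites(6L, 8L, 10)
  sites$role <- "marker_empty"
  sites$logical_bit <- NA_integer_
  corner_motifs <- list(c(grid_index(1, 1, 8), grid_index(1, 2, 8), grid_index(2, 1, 8)),
                        c(grid_index(1, 8, 8), grid_index(1, 7, 8), grid_index(2, 8, 8)),
                        c(grid_index(6, 1, 8), grid_index(5, 1, 8), grid_index(6, 2, 8)),
                        c(grid_index(6, 8, 8), grid_index(6, 7, 8), grid_index(6, 6, 8)))
  sites$role[unlist(corner_motifs)] <- "marker_filled"
  for (j in 1:6) { # char bit j: main site row 2, redundant site row 3
    main <- grid_index(2, j + 1, 8); red <- grid_index(3, j + 1, 8)
    sites$role[c(main, red)] <- "char_bit"
    sites$logical_bit[c(main, red)] <- j
  }
  for (j in 1:6) { # pos bit j: main site row 4, redundant site row 5
    main <- grid_index(4, j + 1, 8); red <- grid_index(5, j + 1, 8)
    sites$role[c(main, red)] <- "pos_bit"
    sites$logical_bit[c(main, red)] <- 6L + j
  }
  if (!redundancy) {
    red_rows <- c(vapply(1:6, function(j) grid_index(3, j + 1, 8), 1L),
                  vapply(1:6, function(j) grid_index(5, j + 1, 8), 1L))
    sites$role[red_rows] <- "marker_empty"
    sites$logical_bit[red_rows] <- NA_integer_
  }
  pattern_rule("rro48", sites, 6L, 6L, pitch = 10)
}

#' @rdname rule_rro12
#' @export
rule_cuboctahedron <- function() {
  a <- 67.5 / 2 # stacked-vertex z separation 67.5 nm
  v <- rbind(c(a, 0, a), c(0, a, a), c(-a, 0, a), c(0, -a, a),      # top square
             c(a, a, 0), c(-a, a, 0), c(-a, -a, 0), c(a, -a, 0),    # equator
             c(a, 0, -a), c(0, a, -a), c(-a, 0, -a), c(0, -a, -a))  # bottom
  sites <- data.frame(x = v[, 1], y = v[, 2], z = v[, 3],
                      role = "marker_empty", logical_bit = NA_integer_)
  ## filled markers 1,2 (top) + 5 (equator); the empty marker at vertex 6
  ## is the 90-degree image of vertex 5, so every quarter-turn of any
  ## pattern either strands a filled marker or occupies a forbidden site
  sites$role[c(1, 2, 5)] <- "marker_filled"
  sites$role[c(6, 12)] <- "marker_empty"
  num_sites <- c(7, 8, 3, 9) # number bits ABCD
  pos_sites <- c(4, 10, 11)  # position bits EFG
  sites$role[num_sites] <- "char_bit"; sites$logical_bit[num_sites] <- 1:4
  sites$role[pos_sites] <- "pos_bit";  sites$logical_bit[pos_sites] <- 5:7
  pattern_rule("cuboctahedron", sites, 4L, 3L, pitch = a * sqrt(2) - 1e-9)
}

#' @rdname rule_rro12
#' @export
rule_tetrapod_dimer <- function() {
  L <- 35
  t_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  A <- L * t_dirs                      # monomer A arm ends
  B <- sweep(L * t_dirs, 2, 2 * L * t_dirs[1, ], `+`) # monomer B, shifted
  v <- rbind(A, B)
  v <- sweep(v, 2, colMeans(v))
  sites <- data.frame(x = v[, 1], y = v[, 2], z = v[, 3],
                      role = "marker_empty", logical_bit = NA_integer_)
  sites$role[c(2, 5)] <- "marker_filled"
  sites$role[8] <- "marker_empty"
  num_sites <- c(3, 4, 6)
  pos_sites <- c(1, 7)
  sites$role[num_sites] <- "char_bit"; sites$logical_bit[num_sites] <- 1:3
  sites$role[pos_sites] <- "pos_bit";  sites$logical_bit[pos_sites] <- 4:5
  pattern_rule("tetrapod_dimer", sites, 3L, 2L, pitch = 35)
}

#' Build the full-template site table for a geometry
#'
#' Emits every candidate docking site of the geometry -- occupied or not --
#' in template-local nm coordinates, together with its role. This is the
#' template the alignment stage registers against: a readout cannot know
#' which sites a particular pattern uses, so all of them are candidates.
#'
#' @param rule a [pattern_rule()] or the `geometry_id` of a built-in rule
#' @return data.frame with `site_id`, `x_nm`, `y_nm`, `z_nm`, `role`,
#'   `logical_bit`
#' @export
build_template <- function(rule) {
  if (is.character(rule)) rule <- builtin_rule(rule)
  stopifnot(inherits(rule, "pattern_rule"))
  data.frame(site_id = seq_len(n_sites(rule)),
             x_nm = rule$sites$x, y_nm = rule$sites$y, z_nm = rule$sites$z,
             role = rule$sites$role, logical_bit = rule$sites$logical_bit)
}

builtin_rule <- function(geometry_id) {
  switch(geometry_id,
         rro12 = rule_rro12(),
         rro24 = rule_rro24(),
         rro48 = rule_rro48(),
         cuboctahedron = rule_cuboctahedron(),
         tetrapod_dimer = rule_tetrapod_dimer(),
         stop("unknown geometry_id: ", geometry_id))
}

#' Export a template as CSV
#'
#' @param rule a [pattern_rule()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_template_csv <- function(rule, path) {
  utils::write.csv(build_template(rule), path, row.names = FALSE, na = "")
  invisible(path)
}
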