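# Acquisition scheme: b-value table, gradient directions, and identification
# of the two key shells (Lb, Hb) used by the sADC and Sindex markers.

#' Build an acquisition scheme
#'
#' Groups the per-volume b-values into shells and resolves the two key shells
#' `key_low_b` (Lb) and `key_high_b` (Hb), plus a b=0 shell. Shell membership
#' is decided within `shell_tolerance` (s/mm^2); every volume must belong to
#' exactly one shell. Direction vectors at b > 0 must be unit norm (1 +- 1e-6);
#' directions for b = 0 volumes are ignored and conventionally stored as zero
#' vectors.
#'
#' @param bvalues numeric vector, one b-value per volume, s/mm^2.
#' @param directions 3 x n numeric matrix of gradient directions (columns are
#'   volumes).
#' @param key_low_b,key_high_b the two key b-values, s/mm^2. Defaults 250 and
#'   1750, the shells from which the markers are computed.
#' @param shell_tolerance assignment tolerance in s/mm^2.
#' @return an object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvalues, directions,
                               key_low_b = 250, key_high_b = 1750,
                               shell_tolerance = 50) {
  if (!is.numeric(bvalues) || length(bvalues) < 3L || any(!is.finite(bvalues)) ||
      any(bvalues < 0))
    stop_validation("'bvalues' must be finite non-negative, one per volume")
  if (!is.matrix(directions) || nrow(directions) != 3L ||
      ncol(directions) != length(bvalues) || any(!is.finite(directions)))
    stop_validation("'directions' must be a finite 3 x n_volumes matrix")
  assert_scalar_number(key_low_b, "key_low_b", positive = TRUE)
  assert_scalar_number(key_high_b, "key_high_b", positive = TRUE)
  assert_scalar_number(shell_tolerance, "shell_tolerance", positive = TRUE)
  if (key_low_b >= key_high_b)
    stop_validation("key_low_b must be smaller than key_high_b")

  nrm <- sqrt(colSums(directions^2))
  bad <- bvalues > shell_tolerance & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop_validation(sprintf(
      "directions at b > 0 must have unit norm (volumes: %s)",
      paste(which(bad), collapse = ", ")))

  # Greedy 1-D clustering of sorted unique b-values into shells.
  ub <- sort(unique(bvalues))
  centers <- numeric(0)
  members <- list()
  for (b in ub) {
    if (length(centers) > 0 && abs(b - centers[length(centers)]) <= shell_tolerance) {
      i <- length(centers)
      members[[i]] <- c(members[[i]], b)
      centers[i] <- mean(members[[i]])
    } else {
      centers <- c(centers, b)
      members[[length(centers)]] <- b
    }
  }
  dist <- abs(outer(bvalues, centers, "-"))
  n_ok <- rowSums(dist <= shell_tolerance)
  if (any(n_ok != 1L))
    stop_validation("every b-value must be assignable to exactly one shell within shell_tolerance")
  shell_of <- max.col(-dist)

  find_shell <- function(target, what) {
    i <- which(abs(centers - target) <= shell_tolerance)
    if (length(i) != 1L)
      stop_validation(sprintf("key shell absent: no unique shell near b = %g (%s)", target, what))
    i
  }
  b0_shell <- which(abs(centers - 0) <= shell_tolerance)
  if (length(b0_shell) != 1L) stop_validation("key shell absent: no b ~ 0 shell")
  lb_shell <- find_shell(key_low_b, "Lb")
  hb_shell <- find_shell(key_high_b, "Hb")
  if (length(unique(c(b0_shell, lb_shell, hb_shell))) != 3L)
    stop_validation("b0, Lb and Hb shells must be distinct")

  structure(list(
    bvalues = as.double(bvalues),
    directions = directions,
    key_low_b = key_low_b,
    key_high_b = key_high_b,
    shell_tolerance = shell_tolerance,
    shell_centers = centers,
    shell_of = shell_of,
    b0_volumes = which(shell_of == b0_shell),
    lb_volumes = which(shell_of == lb_shell),
    hb_volumes = which(shell_of == hb_shell),
    n_volumes = length(bvalues)
  ), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("acquisition_scheme: %d volumes, shells at %s s/mm^2 (Lb = %g, Hb = %g)\n",
              x$n_volumes, paste(signif(x$shell_centers, 4), collapse = ", "),
              x$key_low_b, x$key_high_b))
  invisible(x)
}

#' Read a gradient table from bval/bvec files
#'
#' Reads the row-oriented bval/bvec dialect (volumes as columns): one
#' whitespace-separated row of b-values and three rows of direction
#' components.
#'
#' @param bval_path,bvec_path file paths.
#' @inheritParams acquisition_scheme
#' @return an `acquisition_scheme`.
#' @export
read_scheme <- function(bval_path, bvec_path,
                        key_low_b = 250, key_high_b = 1750,
                        shell_tolerance = 50) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop_io(sprintf("file not found: %s", p))
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3L)
    stop_io("bvec file must contain exactly three non-empty rows")
  rows <- lapply(bvec_lines, function(l) as.double(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  if (length(unique(vapply(rows, length, 1L))) != 1L ||
      length(rows[[1]]) != length(bvals))
    stop_io("bval/bvec row lengths do not match")
  acquisition_scheme(bvals, do.call(rbind, rows),
                     key_low_b = key_low_b, key_high_b = key_high_b,
                     shell_tolerance = shell_tolerance)
}

#' Write a gradient table as bval/bvec files
#'
#' @param scheme an `acquisition_scheme`.
#' @param bval_path,bvec_path output paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(sprintf("%.17g", scheme$bvalues), collapse = " "), bval_path)
  writeLines(apply(scheme$directions, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), bvec_path)
  invisible(NULL)
}

# The default study scheme: one b = 0 volume plus six directions at each of
# the two key shells (250 and 1750 s/mm^2). Directions are the classic
# six-direction dual-gradient set.
default_directions6 <- function() {
  d <- cbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  d / sqrt(2)
}

#' Default three-shell acquisition scheme
#'
#' One b = 0 volume followed by six directions at 250 and six at
#' 1750 s/mm^2 (13 volumes), mirroring a serial mouse-brain DW-EPI protocol.
#'
#' @inheritParams acquisition_scheme
#' @return an `acquisition_scheme` with 13 volumes.
#' @export
default_scheme <- function(key_low_b = 250, key_high_b = 1750, shell_tolerance = 50) {
  dirs <- default_directions6()
  acquisition_scheme(
    bvalues = c(0, rep(key_low_b, 6), rep(key_high_b, 6)),
    directions = cbind(c(0, 0, 0), dirs, dirs),
    key_low_b = key_low_b, key_high_b = key_high_b,
    shell_tolerance = shell_tolerance)
}
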