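# XYZ reading/writing, run configuration, and deterministic fixture
# generation.

#' Read an XYZ file (single or multi-frame)
#'
#' Standard XYZ dialect: atom-count line, comment line, then
#' `element x y z` in Angstrom. A comment line containing `t= <value> fs`
#' (or `t = <value>`) is parsed into the frame time.
#'
#' @param path File path.
#' @return List of frames; each frame is an `n x 3` matrix with attributes
#'   `elements`, `comment` and (if present) `time`. A single-frame file
#'   still returns a length-1 list; attribute `times` on the list collects
#'   frame times.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1 + n > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    comment <- lines[i + 1]
    coords <- matrix(NA_real_, n, 3)
    elements <- character(n)
    for (k in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1 + k]), "\\s+")[[1]]
      if (length(parts) < 4)
        stop("malformed XYZ: bad atom line at line ", i + 1 + k)
      elements[k] <- parts[1]
      coords[k, ] <- as.numeric(parts[2:4])
      if (any(is.na(coords[k, ])))
        stop("malformed XYZ: non-numeric coordinate at line ", i + 1 + k)
    }
    attr(coords, "elements") <- elements
    attr(coords, "comment") <- comment
    tm <- regmatches(comment,
                     regexec("t\\s*=\\s*(-?[0-9.]+)", comment))[[1]]
    if (length(tm) == 2) {
      attr(coords, "time") <- as.numeric(tm[2])
      times <- c(times, as.numeric(tm[2]))
    } else times <- c(times, NA_real_)
    frames[[length(frames) + 1]] <- coords
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  attr(frames, "times") <- times
  frames
}

#' Write geometries to an XYZ file
#'
#' @param geoms A geometry matrix or list of them; each may carry
#'   `elements`, `comment`, `time` attributes (elements default to "C").
#' @param path Output path.
#' @param comments Optional per-frame comment strings (overridden by a
#'   frame's `time` attribute, which is written as `t= <value> fs`).
#' @export
write_xyz <- function(geoms, path, comments = NULL) {
  if (is.matrix(geoms)) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    el <- attr(g, "elements")
    if (is.null(el)) el <- rep("C", nrow(g))
    cm <- if (!is.null(attr(g, "time")))
      sprintf("t= %g fs", attr(g, "time"))
    else if (!is.null(comments)) comments[k]
    else if (!is.null(attr(g, "comment"))) attr(g, "comment")
    else sprintf("frame %d", k)
    writeLines(as.character(nrow(g)), con)
    writeLines(cm, con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f",
                       el, g[, 1], g[, 2], g[, 3]), con)
  }
  invisible(path)
}

#' Read and validate a run configuration file
#'
#' YAML configuration with blocks `model` (name or path), `settings`
#' (passed to [run_settings()]), `sampling` (`n`, `seed`, `window` with
#' `center`/`half_width`), and `output` directory. Unknown top-level keys
#' are an error; the validated config is returned and later echoed into
#' outputs by the command-line driver.
#'
#' @param path YAML file path.
#' @return Named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "settings", "sampling", "analysis", "output")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$model)) stop("config must name a model")
  if (!is.null(cfg$settings))
    cfg$settings <- do.call(run_settings, cfg$settings)
  else cfg$settings <- run_settings()
  structure(cfg, class = "run_config")
}

#' Generate a deterministic fixture
#'
#' Known generators:
#' * `"random_cis"`: seeded random orthonormal orbital sets and normalized
#'   CIS states at two consecutive steps, written as plain-text matrices
#'   (`orbitals_t.txt`, `orbitals_next.txt`, `state<i>_t.txt`, ...).
#' * `"synthetic_occupations"`: closed-form sequential-model occupation
#'   curves as CSV (parameters in `params`).
#' * `"ring_conformers"`: the 38 canonical Boeyens conformers plus the
#'   planar ring as XYZ files.
#'
#' @param spec List with `generator`, `parameters`, `seed`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written.
#' @export
make_fixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- spec$generator
  p <- spec$parameters %||% list()
  seed <- spec$seed %||% 1
  files <- character(0)
  wrt <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.table(x, f, row.names = FALSE, col.names = FALSE)
    files <<- c(files, f)
  }
  if (identical(gen, "random_cis")) {
    set.seed(seed)
    n_occ <- p$n_occ %||% 3
    n_virt <- p$n_virt %||% 3
    eps <- p$rotation %||% 1e-3
    inst <- random_cis_pair(n_occ, n_virt, n_states = p$n_states %||% 2,
                            rotation = eps, dt = p$dt %||% 1e-3)
    wrt(inst$orbitals_t$coefficients, "orbitals_t.txt")
    wrt(inst$orbitals_next$coefficients, "orbitals_next.txt")
    for (m in seq_along(inst$states_t)) {
      wrt(inst$states_t[[m]]$coefficients, sprintf("state%d_t.txt", m))
      wrt(inst$states_next[[m]]$coefficients, sprintf("state%d_next.txt", m))
    }
  } else if (identical(gen, "synthetic_occupations")) {
    t <- p$time %||% seq(0, 1000, by = 0.5)
    occ <- occupations_sequential(t, p$f21 %||% 0.84, p$tau21 %||% 253,
                                  p$f10 %||% 0.70, p$tau10 %||% 391)
    f <- file.path(dir, "occupations.csv")
    utils::write.csv(data.frame(time = t, occ), f, row.names = FALSE)
    files <- c(files, f)
  } else if (identical(gen, "ring_conformers")) {
    tab <- boeyens_table()
    Q <- p$Q %||% 0.5
    for (i in seq_len(nrow(tab))) {
      g <- cremer_pople_inverse(Q, tab$theta[i], tab$phi[i])
      attr(g, "elements") <- c("N", "C", "N", "C", "C", "C")
      f <- file.path(dir, sprintf("conf_%s.xyz", gsub(",", "-",
                                                      tab$label[i])))
      write_xyz(g, f, comments = tab$label[i])
      files <- c(files, f)
    }
    g <- cremer_pople_inverse(0, 0, 0)
    attr(g, "elements") <- c("N", "C", "N", "C", "C", "C")
    f <- file.path(dir, "conf_planar.xyz")
    write_xyz(g, f, comments = "planar")
    files <- c(files, f)
  } else {
    stop("unknown fixture generator '", gen, "'")
  }
  files
}

#' Seeded random CIS instance pair for coupling tests
#'
#' Orbitals at `t + dt` are the orbitals at `t` rotated by
#' `exp(rotation * A)` with `A` a random antisymmetric generator of unit
#' Frobenius norm; CI coefficients change by a random rotation of the same
#' magnitude within the CI space.
#'
#' @param n_occ,n_virt Orbital space sizes.
#' @param n_states Number of CIS states.
#' @param rotation Rotation magnitude (radians).
#' @param dt Time step (fs).
#' @param basis_dim Common-basis dimension (defaults to
#'   `n_occ + n_virt`).
#' @return List with `orbitals_t`, `orbitals_next`, `states_t`,
#'   `states_next`, `dt`.
#' @export
random_cis_pair <- function(n_occ, n_virt, n_states = 2, rotation = 1e-3,
                            dt = 1e-3, basis_dim = n_occ + n_virt) {
  n_orb <- n_occ + n_virt
  O0 <- .random_orthogonal(basis_dim)[, seq_len(n_orb), drop = FALSE]
  A <- .random_antisym(n_orb)
  O1 <- O0 %*% .expm_antisym(rotation * A)   # orbitals mix among themselves
  nci <- n_occ * n_virt
  Tm <- .random_orthogonal(nci)[, seq_len(n_states), drop = FALSE]
  G <- .random_antisym(nci)
  Tn <- .expm_antisym(rotation * G) %*% Tm
  mk <- function(M) lapply(seq_len(n_states), function(m)
    cis_state(matrix(M[, m], n_occ, n_virt), label = m))
  list(orbitals_t = orbital_set(O0, n_occ),
       orbitals_next = orbital_set(O1, n_occ),
       states_t = mk(Tm), states_next = mk(Tn), dt = dt)
}
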