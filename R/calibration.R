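## Calibration harness: empirical size / power of the package's tests under
## simulated Kronecker matrix-variate scenarios. Drives the acceptance
## checks and the command-line `calibrate` workflow.

.cov_from_spec <- function(p, spec) {
  if (is.null(spec)) return(diag(p))
  if (is.matrix(spec)) return(spec)
  do.call(random_covariance,
          c(list(p = p), spec[intersect(names(spec),
                                        c("structure", "rho", "lo", "hi"))]))
}

#' Empirical size and power of the package's tests by simulation
#'
#' Runs one or more named scenarios, each drawing \code{reps} datasets from a
#' Kronecker matrix-variate model and applying the requested test, and
#' reports the empirical rejection rate at the nominal level with its
#' Monte-Carlo standard error. Deterministic given \code{seed}: replicate b
#' of a scenario uses the subject substreams seeded from
#' \code{seed + offset + (b-1) N}, with disjoint offsets across scenarios.
#'
#' @param scenarios a single scenario or a list of scenarios. A scenario is
#'   a list with elements: \code{name} (label), \code{test} (one of
#'   \code{"mean_conservation"}, \code{"sphericity"}, \code{"identity"}),
#'   \code{reps}, \code{r}, \code{c}, \code{N}; and optionally \code{level}
#'   (default 0.05), \code{sigma_r} / \code{sigma_c} (a matrix or a list of
#'   \code{\link{random_covariance}} arguments; default identity),
#'   \code{family}, \code{shape}, \code{delta} (mean shift added to column
#'   \code{shift_col} for a fraction \code{shift_prop} of rows; default 0 =
#'   null scenario), \code{groups} (mean test; default one block of all
#'   columns), \code{subset_cols} (covariance tests; default all columns).
#' @param seed integer master seed.
#' @param out_prefix optional path prefix; writes \code{<prefix>.tsv} and,
#'   when the jsonlite package is available, \code{<prefix>.json}.
#' @return A data frame with columns \code{scenario}, \code{test},
#'   \code{nominal_level}, \code{rejection_rate}, \code{mc_se}, \code{reps}.
#' @export
calibration_run <- function(scenarios, seed = 1L, out_prefix = NULL) {
  if (!is.null(scenarios$test)) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) stop("no scenarios given")
  seed <- as.integer(seed)
  rows <- vector("list", length(scenarios))
  offset <- 0L
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    for (need in c("test", "reps", "r", "c", "N"))
      if (is.null(sc[[need]])) stop("scenario missing field '", need, "'")
    if (!sc$test %in% c("mean_conservation", "sphericity", "identity"))
      stop("unknown test name: ", sc$test)
    reps <- as.integer(sc$reps)
    if (reps < 1L) stop("scenario needs reps >= 1")
    r <- as.integer(sc$r); cc <- as.integer(sc$c); N <- as.integer(sc$N)
    level <- if (is.null(sc$level)) 0.05 else sc$level
    SR <- .cov_from_spec(r, sc$sigma_r)
    SC <- .cov_from_spec(cc, sc$sigma_c)
    M <- matrix(0, r, cc)
    delta <- if (is.null(sc$delta)) 0 else sc$delta
    if (delta != 0) {
      prop <- if (is.null(sc$shift_prop)) 0.1 else sc$shift_prop
      colk <- if (is.null(sc$shift_col)) 1L else as.integer(sc$shift_col)
      M[seq_len(max(1L, round(prop * r))), colk] <- delta
    }
    family <- if (is.null(sc$family)) "gaussian" else sc$family
    shape <- if (is.null(sc$shape)) 1 else sc$shape
    rej <- 0L
    for (b in seq_len(reps)) {
      cfg <- simulation_config(M = M, SigmaR = SR, SigmaC = SC, N = N,
                               family = family, shape = shape,
                               seed = seed + offset + (b - 1L) * N)
      ds <- sample_dataset(cfg)
      pv <- switch(sc$test,
        mean_conservation = {
          grp <- if (is.null(sc$groups)) list(ds$col_ids) else sc$groups
          mean_conservation_test(ds, grp)$p.value
        },
        sphericity = sphericity_test(ds, "columns",
                                     subset = sc$subset_cols)$p.value,
        identity = identity_test(ds, "columns",
                                 subset = sc$subset_cols)$p.value)
      if (pv <= level) rej <- rej + 1L
    }
    offset <- offset + reps * N
    rate <- rej / reps
    rows[[s]] <- data.frame(
      scenario = if (is.null(sc$name)) paste0("scenario_", s) else sc$name,
      test = sc$test, nominal_level = level, rejection_rate = rate,
      mc_se = sqrt(rate * (1 - rate) / reps), reps = reps,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_prefix)) {
    utils::write.table(out, paste0(out_prefix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(out, paste0(out_prefix, ".json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
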