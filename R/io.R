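#' Derive a deterministic child seed
#'
#' Hashes a root seed together with any number of integer indices (replica,
#' stage, scenario, ...) into a seed in `[1, 2^31 - 2]`, using a
#' Lehmer-style multiplicative chain in double precision.  All randomness in
#' the package flows through seeds derived this way from one root seed, so
#' changing the trial count at one stage never perturbs the stream of
#' another, and replica chunks pool reproducibly.
#'
#' @param seed integer root seed.
#' @param ... integer indices identifying the child stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  M <- 2147483647
  x <- as.double(abs(as.integer(seed)) %% M)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) + 1) %% M
  }
  as.integer(x %% (M - 1)) + 1L
}

config_defaults <- list(alpha = 1e-3, p = 0.25, K = 50, gamma = 0.2,
                        model = "gpd", seed = 1, grid_size = 200, refine = TRUE,
                        c_min = 0.05, c_max = 5, a_min = 0.05, a_max = 20,
                        scale_min = 0.05, scale_max = 20,
                        shape_min = 0.05, shape_max = 5)

#' Read and write design configurations
#'
#' `load_config()` reads a structured key/value (YAML) file into a validated
#' [design_config()], filling documented defaults for missing keys (`m`
#' defaults to [conservative_stage_count()]); unknown keys are rejected by
#' name.  `save_config()` writes a configuration back; the two round-trip
#' losslessly.
#'
#' Recognized keys: `model`, `alpha`, `p`, `m`, `K`, `gamma`, `s1`, `seed`,
#' `grid_size`, `refine`, `c_min`, `c_max`, `a_min`, `a_max`, `scale_min`,
#' `scale_max`, `shape_min`, `shape_max`.  `s1` (the first threshold on the
#' reciprocal scale) is required.
#'
#' @param path file path.
#' @return `load_config()`: a [design_config()]. `save_config()`: the path,
#'   invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c(names(config_defaults), "s1", "m")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw[["s1"]])) stop("missing required key: s1", call. = FALSE)
  get_key <- function(k) raw[[k]] %||% config_defaults[[k]]
  alpha <- get_key("alpha"); p <- get_key("p")
  if (!(is.numeric(alpha) && is.numeric(p) && alpha > 0 && alpha < p && p < 1))
    stop("invalid keys 'alpha'/'p': need 0 < alpha < p < 1", call. = FALSE)
  m <- raw[["m"]] %||% conservative_stage_count(alpha, p)
  est_cfg <- estimator_config(
    c_range = c(get_key("c_min"), get_key("c_max")),
    a_range = c(get_key("a_min"), get_key("a_max")),
    scale_range = c(get_key("scale_min"), get_key("scale_max")),
    shape_range = c(get_key("shape_min"), get_key("shape_max")),
    grid_size = get_key("grid_size"), refine = get_key("refine"))
  design_config(alpha = alpha, p = p, m = m, K = get_key("K"),
                gamma = get_key("gamma"), s1_tilde = raw[["s1"]],
                model = get_key("model"), estimator_cfg = est_cfg,
                seed = get_key("seed"))
}

#' @rdname load_config
#' @param config a [design_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  ec <- config$estimator_cfg
  yaml::write_yaml(list(
    model = config$model, alpha = config$alpha, p = config$p, m = config$m,
    K = config$K, gamma = config$gamma, s1 = config$s1_tilde,
    seed = config$seed, grid_size = ec$grid_size, refine = ec$refine,
    c_min = ec$c_range[1], c_max = ec$c_range[2],
    a_min = ec$a_range[1], a_max = ec$a_range[2],
    scale_min = ec$scale_range[1], scale_max = ec$scale_range[2],
    shape_min = ec$shape_range[1], shape_max = ec$shape_range[2]), path)
  invisible(path)
}

stage_log_header <- c("replica_id", "stage", "threshold", "n_trials",
                      "n_exceed", "p_hat", "ci_lo", "ci_hi", "c_hat", "a_hat",
                      "objective")

#' Persist and replay sequential stage logs
#'
#' `write_stage_log()` appends the per-stage audit trail of a
#' [run_splitting()] result to a CSV with fixed header
#' `replica_id, stage, threshold, n_trials, n_exceed, p_hat, ci_lo, ci_hi,
#' c_hat, a_hat, objective`, all numbers at 9 significant digits ('.' decimal
#' separator, no grouping).  For the Weibull model the `c_hat`/`a_hat` columns
#' carry shape and scale respectively.  `read_stage_log()` parses the file
#' back into a list of per-stage records, validating that thresholds increase
#' strictly within each replica; malformed rows are reported with their line
#' number.  An empty file yields an empty list.
#'
#' @param result a `"splitting_result"` from [run_splitting()].
#' @param path CSV file path.
#' @param replica_id integer identifier written with each row.
#' @param append logical; append to an existing log (default `FALSE`).
#' @return `write_stage_log()`: the path, invisibly. `read_stage_log()`: a
#'   list of stage records (one named list per row).
#' @export
write_stage_log <- function(result, path, replica_id = 1L, append = FALSE) {
  stopifnot(inherits(result, "splitting_result"))
  fmt <- function(x) ifelse(is.na(x), "NA", trimws(formatC(x, digits = 9, format = "g")))
  rows <- vapply(result$stages, function(st) {
    prm <- st$est_params
    ch <- if (result$model == "gpd") prm$c else prm$shape
    ah <- if (result$model == "gpd") prm$a else prm$scale
    paste(c(replica_id, st$stage, fmt(st$threshold), result$config$K,
            st$n_exceed, fmt(st$p_hat), fmt(st$interval[1]), fmt(st$interval[2]),
            fmt(ch), fmt(ah), fmt(st$objective)), collapse = ",")
  }, character(1))
  lines <- if (append && file.exists(path)) rows
           else c(paste(stage_log_header, collapse = ","), rows)
  cat(lines, file = path, sep = "\n", append = append && file.exists(path))
  invisible(path)
}

#' @rdname write_stage_log
#' @export
read_stage_log <- function(path) {
  if (!file.exists(path)) stop("stage log not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) return(list())
  if (!identical(strsplit(lines[1], ",")[[1]], stage_log_header))
    stop("stage log header mismatch at line 1", call. = FALSE)
  if (length(lines) == 1L) return(list())
  recs <- vector("list", length(lines) - 1L)
  for (i in 2:length(lines)) {
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) != length(stage_log_header))
      stop(sprintf("malformed stage log row at line %d: expected %d fields, got %d",
                   i, length(stage_log_header), length(parts)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts))
    bad <- which(is.na(vals) & parts != "NA")
    if (length(bad) > 0)
      stop(sprintf("malformed numeric field '%s' at line %d", parts[bad[1]], i),
           call. = FALSE)
    recs[[i - 1L]] <- stats::setNames(as.list(vals), stage_log_header)
  }
  by_rep <- split(recs, vapply(recs, function(r) r$replica_id, numeric(1)))
  for (rr in by_rep) {
    th <- vapply(rr, function(r) r$threshold, numeric(1))
    st <- vapply(rr, function(r) r$stage, numeric(1))
    if (any(diff(th[order(st)]) <= 0))
      stop("stage log validation failed: thresholds are not strictly increasing within replica ",
           rr[[1]]$replica_id, call. = FALSE)
  }
  recs
}
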