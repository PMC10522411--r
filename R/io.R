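#' Load an experiment configuration
#'
#' Configurations are flat JSON objects with optional blocks:
#' `variant` (name), `params` (overrides of [default_parameters()] fields),
#' `optimizer` (fields of [opt_options()]), `solver` (fields of
#' [ss_options()]), `seed`, and `grid` (`from`, `to`, `n`, `log`).  Unknown
#' keys anywhere are an error; parameter overrides are validated eagerly.
#'
#' @param path path to a JSON file.
#' @return A validated `cgram_config` list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("variant", "params", "optimizer", "solver", "seed", "grid")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  variant <- raw$variant %||% "full"
  if (!variant %in% c("core", "two_pathway", "full"))
    stop("config field 'variant' must be core, two_pathway or full",
         call. = FALSE)

  params <- default_parameters()
  if (!is.null(raw$params)) {
    ov <- as.list(raw$params)
    bad <- setdiff(names(ov), PARAM_NAMES)
    if (length(bad))
      stop("unknown parameter key(s) in config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    params[names(ov)] <- ov
    validate_parameter_set(params)
  }

  optimizer <- opt_options()
  if (!is.null(raw$optimizer)) {
    ov <- as.list(raw$optimizer)
    bad <- setdiff(names(ov), setdiff(names(optimizer), "solver"))
    if (length(bad))
      stop("unknown optimizer key(s) in config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    optimizer[names(ov)] <- ov
    optimizer$nm_max_iter <- as.integer(optimizer$nm_max_iter)
  }

  solver <- ss_options()
  if (!is.null(raw$solver)) {
    ov <- as.list(raw$solver)
    bad <- setdiff(names(ov), names(solver))
    if (length(bad))
      stop("unknown solver key(s) in config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    solver[names(ov)] <- ov
    solver$max_steps <- as.integer(solver$max_steps)
  }
  optimizer$solver <- solver

  grid <- NULL
  if (!is.null(raw$grid)) {
    g <- as.list(raw$grid)
    bad <- setdiff(names(g), c("from", "to", "n", "log"))
    if (length(bad))
      stop("unknown grid key(s) in config: ", paste(bad, collapse = ", "),
           call. = FALSE)
    g$log <- g$log %||% TRUE
    grid <- if (isTRUE(g$log)) log_grid(g$from, g$to, g$n)
            else seq(g$from, g$to, length.out = g$n)
  }

  structure(list(variant = variant, params = params,
                 optimizer = optimizer, solver = solver,
                 seed = raw$seed %||% 1L, grid = grid),
            class = "cgram_config")
}

# all-numeric columns of a sweep table, for lossless CSV round trips
SWEEP_CHR_COLS <- c("regime", "mode")
SWEEP_LGL_COLS <- c("converged")

#' Write and read sweep tables
#'
#' Sweeps are persisted as an RFC-4180 CSV (one row per grid point, all
#' floating-point cells at 17 significant digits so the round trip is
#' lossless) plus a JSON metadata sidecar `<path>.meta.json` recording the
#' sweep type, variant, fixed parameters, grid and seed.  `read_sweep()`
#' is the exact inverse; it fails naming the missing columns on a schema
#' mismatch.
#'
#' @param sweep a `cgram_sweep`.
#' @param path CSV file path.
#' @return `write_sweep()` returns `path` invisibly; `read_sweep()` a
#'   `cgram_sweep`.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "cgram_sweep"))
  tab <- sweep$table
  out <- tab
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  jsonlite::write_json(sweep$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("sweep file not found: ", path,
                               call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mu", ALLOC_NAMES, STATE_NAMES, "regime", "converged")
  missing_cols <- setdiff(need, names(tab))
  if (nrow(tab) > 0 && length(missing_cols))
    stop("sweep schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (nm in intersect(SWEEP_CHR_COLS, names(tab)))
    tab[[nm]] <- as.character(tab[[nm]])
  for (nm in intersect(SWEEP_LGL_COLS, names(tab)))
    tab[[nm]] <- as.logical(tab[[nm]])
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  new_sweep(tab, meta)
}

#' Canned desk-scale sweeps for tests and demos
#'
#' Generates three tiny deterministic sweeps: a 5-point core carbon-uptake
#' sweep, a 5-point carbon-to-nitrogen sweep of the full model, and a
#' 10-triplet random-parametrization sample with a fixed seed.  They are
#' regenerated on demand (never stored) and use slightly relaxed optimizer
#' tolerances to stay fast.
#'
#' @param seed seed for the random sample.
#' @return A named list of three `cgram_sweep` objects.
#' @export
fixture_sweeps <- function(seed = 101) {
  opts <- opt_options(nm_tol = 1e-8, nm_max_iter = 400L,
                      solver = ss_options(rtol = 1e-6, atol = 1e-8))
  list(
    kc_core = sweep_carbon_uptake(grid = log_grid(1e-1, 1e3, 5),
                                  options = opts),
    cn_full = sweep_cn_ratio(kKre_values = 10.0,
                             cn_grid = seq(0, 20, length.out = 5),
                             options = opts),
    random = random_parameter_sample(n_triplets = 10, seed = seed,
                                     cn_ratios = 0, kKre_values = 10.0,
                                     options = opts))
}
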