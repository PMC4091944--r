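#' Run configuration: every tunable parameter in one flat list
#'
#' Serializable as a `key = value` text file.  Unknown keys are rejected so
#' that typos cannot silently fall back to defaults.
#'
#' @param ... overrides of the documented defaults (see [graph_config()] and
#'   [solver_params()]), plus `spacing_row_mm`, `spacing_col_mm`, `seed`.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- c(unclass(graph_config()),
                unclass(solver_params()),
                list(spacing_row_mm = 1, spacing_col_mm = 1, seed = 0))
  # auto penalties serialize as 0 (= derive from the graph)
  defaults$r1 <- 0; defaults$r2 <- 0
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @export
#' @method print run_config
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a run configuration as a key = value file
#'
#' @param config a [run_config].
#' @param path text file path.
#' @return `read_run_config`: a [run_config]; `write_run_config`: the path,
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm, if (is.logical(v)) ifelse(v, "true", "false")
            else format(v, digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  parsed <- lapply(vals, function(v) {
    if (v %in% c("true", "false")) return(v == "true")
    suppressWarnings(n <- as.numeric(v))
    if (is.na(n)) v else n
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}

# split a run_config into the typed parameter objects
config_graph <- function(cfg) {
  graph_config(patch_radius = cfg$patch_radius, window_radius = cfg$window_radius,
               sigma = cfg$sigma, eps = cfg$eps, symmetric = cfg$symmetric)
}
config_solver <- function(cfg) {
  solver_params(lambda = cfg$lambda,
                r1 = if (cfg$r1 > 0) cfg$r1 else NULL,
                r2 = if (cfg$r2 > 0) cfg$r2 else NULL,
                relax = cfg$relax, cg_tol = cfg$cg_tol,
                cg_maxiter = cfg$cg_maxiter, outer_tol = cfg$outer_tol,
                residual_tol = cfg$residual_tol, max_outer = cfg$max_outer,
                threshold = cfg$threshold)
}
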