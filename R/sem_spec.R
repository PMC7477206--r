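#' Structural equation model specifications
#'
#' A `sem_spec` describes a latent-variable structural model in RAM form:
#' latent variables measured by observed indicators, directed structural
#' paths among observed and latent variables, covariances (including
#' correlated indicator residuals), and an identification convention.
#'
#' @name sem_spec_module
NULL

#' Create a structural equation model specification
#'
#' @param observed Character vector of observed variable names, in the order
#'   they appear in the data/covariance matrix.
#' @param latents Named list: latent name -> character vector of indicator
#'   names (each indicator must be an observed variable).
#' @param paths Data frame with columns `from`, `to` (and optionally `free`,
#'   `value`) giving directed structural paths. Defaults: free paths.
#' @param covariances Data frame with columns `a`, `b` (optionally `free`,
#'   `value`): covariances between exogenous variables or between indicator
#'   residuals (correlated residuals).
#' @param identification `"marker"` fixes the first loading of every latent
#'   to 1 (default, used for fitting); `"none"` leaves all loadings free,
#'   which is not identified for fitting but convenient for evaluating a
#'   fully specified parameter vector (e.g. a simulation ground truth).
#' @return An object of class `sem_spec`.
#' @export
sem_spec <- function(observed, latents = list(), paths = NULL,
                     covariances = NULL,
                     identification = c("marker", "none")) {
  identification <- match.arg(identification)
  observed <- as.character(observed)
  if (anyDuplicated(observed)) stop("duplicate observed variable names")
  lat_names <- names(latents)
  if (length(latents) && (is.null(lat_names) || any(lat_names == "")))
    stop("latents must be a named list")
  if (any(lat_names %in% observed))
    stop("latent names clash with observed variable names")
  for (L in lat_names) {
    ind <- latents[[L]]
    if (!all(ind %in% observed))
      stop("indicators of '", L, "' not all observed: ",
           paste(setdiff(ind, observed), collapse = ", "))
    if (length(ind) < 1L) stop("latent '", L, "' has no indicators")
  }
  all_vars <- c(observed, lat_names)

  norm_edges <- function(df, cols) {
    if (is.null(df)) {
      empty <- stats::setNames(
        list(character(0), character(0), logical(0), numeric(0)),
        c(cols, "free", "value"))
      return(as.data.frame(empty))
    }
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop("edge table needs columns ", paste(cols, collapse = ", "))
    if (is.null(df$free)) df$free <- TRUE
    if (is.null(df$value)) df$value <- NA_real_
    df$free <- as.logical(df$free)
    df$value <- as.numeric(df$value)
    for (cc in cols) {
      df[[cc]] <- as.character(df[[cc]])
      if (!all(df[[cc]] %in% all_vars))
        stop("unknown variable(s): ",
             paste(setdiff(df[[cc]], all_vars), collapse = ", "))
    }
    df[, c(cols, "free", "value")]
  }
  paths <- norm_edges(paths, c("from", "to"))
  covariances <- norm_edges(covariances, c("a", "b"))

  if (nrow(paths)) {
    # structural graph must be acyclic (indicator edges always point
    # latent -> observed and cannot create cycles with structural paths
    # unless an indicator is also a structural source, which we allow)
    g_edges <- rbind(paths[, c("from", "to")],
                     do.call(rbind, lapply(lat_names, function(L)
                       data.frame(from = L, to = latents[[L]]))))
    if (has_cycle(g_edges, all_vars))
      stop("directed path graph contains a cycle")
  }

  spec <- list(observed = observed, latents = latents, paths = paths,
               covariances = covariances, identification = identification)
  class(spec) <- "sem_spec"
  spec
}

has_cycle <- function(edges, vars) {
  adj <- split(edges$to, factor(edges$from, levels = vars))
  state <- stats::setNames(integer(length(vars)), vars) # 0 new 1 open 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in vars) if (state[[v]] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' @export
print.sem_spec <- function(x, ...) {
  pt <- sem_ptable(x)
  cat("sem_spec: ", length(x$observed), " observed, ",
      length(x$latents), " latent; ", sum(pt$free), " free parameters, df = ",
      model_df(x), "\n", sep = "")
  invisible(x)
}

#' Parameter table of a specification
#'
#' Expands a `sem_spec` into one row per model parameter (RAM matrices `A`
#' for directed edges, `S` for symmetric ones), with fixed values and
#' lavaan-style labels (`f=~ind` loadings, `to~from` paths, `a~~b`
#' (co)variances). Free parameters appear in the order used by the `theta`
#' vectors throughout the package.
#'
#' @param spec A [sem_spec()].
#' @return Data frame with columns `matrix,row,col,free,value,label,type`.
#' @export
sem_ptable <- function(spec) {
  all_vars <- c(spec$observed, names(spec$latents))
  idx <- stats::setNames(seq_along(all_vars), all_vars)
  rows <- list()
  add <- function(matrix, i, j, free, value, label, type)
    rows[[length(rows) + 1L]] <<- data.frame(
      matrix = matrix, row = i, col = j, free = free, value = value,
      label = label, type = type)

  for (L in names(spec$latents)) {
    ind <- spec$latents[[L]]
    for (k in seq_along(ind)) {
      fixed_marker <- spec$identification == "marker" && k == 1L
      add("A", idx[[ind[k]]], idx[[L]],
          free = !fixed_marker,
          value = if (fixed_marker) 1 else NA_real_,
          label = paste0(L, "=~", ind[k]), type = "loading")
    }
  }
  if (nrow(spec$paths)) for (r in seq_len(nrow(spec$paths))) {
    p <- spec$paths[r, ]
    add("A", idx[[p$to]], idx[[p$from]], free = p$free,
        value = if (p$free) NA_real_ else p$value,
        label = paste0(p$to, "~", p$from), type = "path")
  }
  endo <- unique(c(unlist(spec$latents), spec$paths$to))
  for (v in all_vars)
    add("S", idx[[v]], idx[[v]], free = TRUE, value = NA_real_,
        label = paste0(v, "~~", v),
        type = "variance")
  if (nrow(spec$covariances)) for (r in seq_len(nrow(spec$covariances))) {
    cv <- spec$covariances[r, ]
    add("S", idx[[cv$a]], idx[[cv$b]], free = cv$free,
        value = if (cv$free) NA_real_ else cv$value,
        label = paste0(cv$a, "~~", cv$b), type = "covariance")
  }
  pt <- do.call(rbind, rows)
  pt$endogenous <- all_vars[pt$row] %in% endo & pt$type == "variance"
  pt
}

#' Model degrees of freedom
#'
#' For covariance-based maximum likelihood with saturated means:
#' `p(p+1)/2` sample moments minus the number of free parameters.
#'
#' @param spec A [sem_spec()].
#' @param p Number of observed variables (defaults to those in the spec).
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec, p = length(spec$observed)) {
  pt <- sem_ptable(spec)
  df <- p * (p + 1) / 2 - sum(pt$free)
  if (df < 0)
    stop("model is not identified: ", sum(pt$free), " free parameters but ",
         p * (p + 1) / 2, " sample moments")
  as.integer(df)
}

#' Number of free parameters
#' @param spec A [sem_spec()].
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(spec) sum(sem_ptable(spec)$free)

#' Fix all structural paths touching a variable to zero
#'
#' Builds the nested comparison model: every free directed structural path
#' with `variable` as source or target is fixed at 0. Measurement loadings
#' and covariances are retained, so the free-parameter count drops by
#' exactly the number of such paths.
#'
#' @param spec A [sem_spec()].
#' @param variable Observed or latent variable name.
#' @return The constrained `sem_spec`.
#' @export
constrain_variable_paths <- function(spec, variable) {
  all_vars <- c(spec$observed, names(spec$latents))
  if (!variable %in% all_vars)
    stop("unknown variable '", variable, "'")
  hit <- spec$paths$free &
    (spec$paths$from == variable | spec$paths$to == variable)
  spec$paths$free[hit] <- FALSE
  spec$paths$value[hit] <- 0
  spec
}

#' Default frontoparietal structural model
#'
#' The full latent-variable model relating age, the cerebrovascular risk
#' score (CVR) and white-matter-hyperintensity load (WMH; all observed) to
#' three latent variables: frontoparietal grey-matter volume (`gm`, measured
#' by six regional volumes: angular gyrus `ag`, precuneus `prc`, cingulate
#' gyrus `cg`, superior frontal gyrus `sfg`, frontal pole `fp`, middle
#' temporal gyrus `mtg`), white-matter integrity of the superior
#' longitudinal fasciculus (`wm`, measured by `icvf` and `od`) and executive
#' function (`ef`, measured by the reaction-time score `rt` and the
#' pairs-matching score `pairs`; both oriented so higher = better).
#'
#' Directed paths: age and CVR to WMH; age, CVR and WMH to each of `gm` and
#' `wm`; `gm` and `wm` to `ef`. Age and CVR covary. Correlated residuals
#' among grey-matter indicators are configuration, not search; the default
#' pairs are `ag`-`prc` and `sfg`-`fp`.
#'
#' @param correlated_residuals List of 2-element character vectors naming
#'   indicator pairs whose residuals covary.
#' @param identification Passed to [sem_spec()].
#' @return A [sem_spec()].
#' @export
fp_sem_spec <- function(correlated_residuals = list(c("ag", "prc"),
                                                    c("sfg", "fp")),
                        identification = "marker") {
  observed <- c("age", "cvr", "wmh", "ag", "prc", "cg", "sfg", "fp", "mtg",
                "icvf", "od", "rt", "pairs")
  latents <- list(
    gm = c("ag", "prc", "cg", "sfg", "fp", "mtg"),
    wm = c("icvf", "od"),
    ef = c("rt", "pairs")
  )
  paths <- data.frame(
    from = c("age", "cvr", "age", "cvr", "wmh", "age", "cvr", "wmh",
             "gm", "wm"),
    to   = c("wmh", "wmh", "gm", "gm", "gm", "wm", "wm", "wm",
             "ef", "ef")
  )
  covs <- data.frame(a = "age", b = "cvr")
  for (pr in correlated_residuals) {
    stopifnot(length(pr) == 2L)
    covs <- rbind(covs, data.frame(a = pr[1], b = pr[2]))
  }
  sem_spec(observed, latents, paths, covs, identification = identification)
}

#' Write a model specification as JSON
#'
#' @param spec A [sem_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sem_spec <- function(spec, path) {
  jsonlite::write_json(
    list(observed = spec$observed, latents = spec$latents,
         paths = spec$paths, covariances = spec$covariances,
         identification = spec$identification),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model specification from JSON (or YAML)
#'
#' @param path File with `observed`, `latents`, `paths`, `covariances`,
#'   `identification` sections.
#' @return A [sem_spec()].
#' @export
read_sem_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML model specs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  to_df <- function(x) if (is.null(x) || (is.data.frame(x) && !nrow(x)) ||
                           length(x) == 0) NULL else as.data.frame(x)
  sem_spec(unlist(obj$observed), lapply(obj$latents, unlist),
           paths = to_df(obj$paths), covariances = to_df(obj$covariances),
           identification = if (is.null(obj$identification)) "marker"
                            else obj$identification)
}
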