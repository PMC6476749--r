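#' Akaike weights
#'
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` with
#' `delta_m = AIC_m - min(AIC)`; invariant to adding a constant to all
#' AIC values.
#'
#' @param aic numeric vector of AIC values.
#' @return weights summing to 1.
#' @export
aic_weights <- function(aic) {
  if (!length(aic)) stop("need at least one model")
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Backward stepwise model selection by AIC
#'
#' Starting from a full model, repeatedly drops the single covariate
#' (from the eligible blocks) whose removal most reduces AIC, and stops
#' when no single removal reduces it.  Ties are broken in favour of the
#' drop leaving fewer parameters, then alphabetically by `block.name`.
#' By default the detection block is not reduced below intercept + effort
#' (effort is retained as a detection covariate throughout); pass
#' `blocks` to change which blocks are eligible.
#'
#' Candidate fits that fail outright are recorded and skipped.  The
#' returned Akaike weights are computed over the stepwise path models
#' (the one-model-per-step table); set `weights_over = "all"` to weight
#' over every candidate fitted along the way.
#'
#' An explicit `drop_order` (list of `c(block, name)` pairs) bypasses the
#' greedy search and fits exactly that nested sequence, for reproducing a
#' predetermined table.
#'
#' @param det,cov,other_psi data as for [occu_fit()].
#' @param spec the full-model [occu_spec()].
#' @param blocks blocks whose covariates may be dropped (default all
#'   occupancy/dynamics blocks, not detection).
#' @param weights_over `"path"` or `"all"`.
#' @param drop_order optional explicit sequence of drops.
#' @param control optimizer settings forwarded to [occu_fit()].
#' @return an object of class `occu_selection`: a list with `table`
#'   (formula, logLik, K, AIC, wAIC per path model), `fits` (path fits),
#'   `best` (index of the minimum-AIC model), `all_models` (every
#'   candidate's formula and AIC) and `failures`.
#' @export
backward_stepwise <- function(det, cov, spec, other_psi = NULL,
                              blocks = if (spec$dynamic)
                                c("psi", "gamma", "phi") else "psi",
                              weights_over = c("path", "all"),
                              drop_order = NULL, control = list()) {
  weights_over <- match.arg(weights_over)
  fit1 <- function(sp) occu_fit(det, cov, sp, other_psi = other_psi,
                                hessian = FALSE, control = control)
  failures <- character(0)
  all_models <- list()
  note <- function(sp, fit) {
    all_models[[length(all_models) + 1L]] <<-
      data.frame(model = format(sp), AIC = if (is.null(fit)) NA else fit$AIC)
  }
  cur <- tryCatch(fit1(spec), error = function(e)
    stop("full model failed to fit: ", conditionMessage(e)))
  note(spec, cur)
  path <- list(cur)
  if (!is.null(drop_order)) {
    sp <- spec
    for (d in drop_order) {
      sp <- spec_drop(sp, d[[1]], d[[2]])
      f <- tryCatch(fit1(sp), error = function(e) NULL)
      if (is.null(f)) { failures <- c(failures, format(sp)); next }
      note(sp, f)
      path[[length(path) + 1L]] <- f
    }
  } else {
    repeat {
      cand <- list()
      for (b in intersect(blocks, c("psi", "gamma", "phi", "p")))
        for (nm in path[[length(path)]]$spec[[b]])
          cand[[length(cand) + 1L]] <- c(b, nm)
      if (!length(cand)) break
      fits <- lapply(cand, function(d) {
        sp <- spec_drop(path[[length(path)]]$spec, d[1], d[2])
        f <- tryCatch(fit1(sp), error = function(e) NULL)
        if (is.null(f)) failures <<- c(failures, paste0(d[1], ".", d[2]))
        else note(sp, f)
        f
      })
      ok <- !vapply(fits, is.null, TRUE)
      if (!any(ok)) break
      aics <- vapply(fits[ok], `[[`, 0, "AIC")
      ks <- vapply(fits[ok], `[[`, 0, "K")
      lab <- vapply(cand[ok], function(d) paste0(d[1], ".", d[2]), "")
      ord <- order(round(aics, 10), ks, lab)
      best <- ord[1L]
      if (aics[best] >= path[[length(path)]]$AIC) break
      path[[length(path) + 1L]] <- fits[ok][[best]]
    }
  }
  # report best-first, as selection tables are conventionally printed
  path <- rev(path)
  tab <- data.frame(
    model = vapply(path, function(f) format(f$spec), ""),
    logLik = vapply(path, `[[`, 0, "logLik"),
    K = vapply(path, `[[`, 0, "K"),
    AIC = vapply(path, `[[`, 0, "AIC"))
  all_tab <- do.call(rbind, all_models)
  tab$wAIC <- if (weights_over == "path") aic_weights(tab$AIC) else
    aic_weights(all_tab$AIC)[match(tab$model, all_tab$model)]
  out <- list(table = tab, fits = path, best = which.min(tab$AIC),
              all_models = all_tab, failures = failures,
              weights_over = weights_over)
  class(out) <- "occu_selection"
  out
}

#' @export
print.occu_selection <- function(x, digits = 2, ...) {
  cat("Backward stepwise AIC selection (", nrow(x$table), " path models, ",
      nrow(x$all_models), " fits)\n", sep = "")
  tab <- x$table
  tab$logLik <- round(tab$logLik, digits)
  tab$AIC <- round(tab$AIC, digits)
  tab$wAIC <- round(tab$wAIC, digits)
  print(tab, row.names = FALSE)
  if (length(x$failures))
    cat("failed candidates skipped:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.occu_selection <- function(x, ...) x$table

#' Best model of a selection trace
#' @param x an `occu_selection`.
#' @return the minimum-AIC [occu_fit()].
#' @export
best_fit <- function(x) x$fits[[x$best]]
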