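# The two variable-selection procedures applied within each preceding
# study: univariable prescreening and AIC-based backward elimination.

# Fast univariable screen on matrices.  The slope t-test in a simple
# regression is equivalent to the correlation t-test, so the whole screen
# is one cor() call.  Returns a list with p-values and the selection mask.
univariable_screen <- function(X, y, alpha) {
  n <- nrow(X)
  sds <- col_sds(X)
  const <- sds == 0
  r <- rep(NA_real_, ncol(X))
  if (any(!const)) {
    r[!const] <- as.vector(cor(X[, !const, drop = FALSE], y))
  }
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  if (any(const)) {
    warn(paste0("constant column(s) treated as not selected: ",
                paste(colnames(X)[const], collapse = ", ")))
  }
  list(p = p, selected = !is.na(p) & p <= alpha)
}

col_sds <- function(X) {
  apply(X, 2, sd)
}

#' Univariable variable selection
#'
#' Screens each of the candidate columns independently: the outcome is
#' regressed on that variable alone (with intercept) and the variable is
#' selected when the two-sided p-value of its slope is at most
#' `alpha_in`.  No multiplicity correction is applied — that is the
#' point of emulating the procedure.  Constant columns get an undefined
#' p-value and are treated as not selected, with a warning.
#'
#' @param data A study tibble containing the candidate columns and the
#'   outcome column.
#' @param alpha_in Inclusion threshold in (0, 1); the emulated practice
#'   uses 0.05 or 0.2.
#' @param outcome Name of the outcome column.
#'
#' @return A `prs_selection` tibble with columns `variable`, `p_value`,
#'   `selected`, and attributes `method` (`"univariable"`), `threshold`
#'   and `study_n`.
#' @export
univariable_select <- function(data, alpha_in = 0.05, outcome = "y") {
  stopifnot(alpha_in > 0, alpha_in < 1)
  X <- as.matrix(data[, setdiff(names(data), outcome), drop = FALSE])
  y <- data[[outcome]]
  scr <- univariable_screen(X, y, alpha_in)
  new_selection(
    tibble(variable = colnames(X), p_value = scr$p,
           selected = scr$selected),
    method = "univariable", threshold = alpha_in, study_n = nrow(X)
  )
}

# Greedy AIC backward elimination on matrices.  Uses the exact
# single-deletion identity RSS(A \ j) = RSS(A) + b_j^2 / [(X'X)^-1]_jj,
# so each elimination step needs one Cholesky inversion instead of k
# refits.  Ties within 1e-10 are broken toward the earlier column.
backward_screen <- function(X, y, trace = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2) abort("insufficient data: full model is not estimable")
  Xd <- cbind(1, X)
  G <- crossprod(Xd)
  Gy <- as.vector(crossprod(Xd, y))
  yty <- sum(y^2)
  # RSS below machine precision relative to the outcome scale is
  # indistinguishable from an exact fit; flooring it keeps n * log(RSS)
  # comparisons from amplifying cancellation noise in near-noiseless data.
  rss_floor <- max(1e-12 * yty, .Machine$double.xmin)
  active <- seq_len(p)
  dropped <- NA_character_
  aic_path <- numeric(0)
  repeat {
    idx <- c(1L, active + 1L)
    ch <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) abort("singular design: columns are linearly dependent")
    Gi <- chol2inv(ch)
    b <- as.vector(Gi %*% Gy[idx])
    rss <- max(yty - sum(b * Gy[idx]), rss_floor)
    k <- length(idx)
    cur_aic <- gaussian_aic(rss, n, k)
    aic_path <- c(aic_path, cur_aic)
    if (length(active) == 0) break
    drop_rss <- pmax(rss + b[-1]^2 / diag(Gi)[-1], rss_floor)
    drop_aic <- gaussian_aic(drop_rss, n, k - 1)
    best <- min(drop_aic)
    if (best < cur_aic - 1e-10) {
      j <- which(drop_aic <= best + 1e-10)[1]
      dropped <- c(dropped, colnames(X)[active[j]])
      active <- active[-j]
    } else {
      break
    }
  }
  mask <- rep(FALSE, p)
  mask[active] <- TRUE
  trace_tbl <- NULL
  if (trace) {
    trace_tbl <- tibble(step = seq_along(aic_path) - 1L,
                        dropped = dropped, aic = aic_path)
  }
  list(selected = mask, trace = trace_tbl)
}

#' Backward elimination with the AIC
#'
#' Starts from the model containing all candidate columns plus an
#' intercept and greedily deletes variables: at each step the AIC of every
#' single-variable deletion is evaluated and the best deletion is applied
#' if its AIC is strictly below the current model's; the procedure stops
#' when no deletion improves the AIC.  The intercept is never removed.
#' Because every candidate is a single column, the least-significant and
#' best-AIC deletions coincide at each step.
#'
#' @inheritParams univariable_select
#' @return A `prs_selection` tibble with columns `variable`, `selected`,
#'   and attributes `method` (`"backward"`), `study_n` and `steps` (a
#'   tibble logging the AIC path).
#' @export
backward_eliminate <- function(data, outcome = "y") {
  X <- as.matrix(data[, setdiff(names(data), outcome), drop = FALSE])
  y <- data[[outcome]]
  scr <- backward_screen(X, y, trace = TRUE)
  new_selection(
    tibble(variable = colnames(X), selected = scr$selected),
    method = "backward", threshold = NA_real_, study_n = nrow(X),
    steps = scr$trace
  )
}

new_selection <- function(tbl, method, threshold, study_n, steps = NULL) {
  structure(tbl,
            class = c("prs_selection", class(tbl)),
            method = method, threshold = threshold, study_n = study_n,
            steps = steps)
}

#' @export
print.prs_selection <- function(x, ...) {
  cat("<prs_selection> method = ", attr(x, "method"),
      if (!is.na(attr(x, "threshold"))) {
        paste0(" (alpha_in = ", attr(x, "threshold"), ")")
      },
      ", study n = ", attr(x, "study_n"),
      ", selected ", sum(x$selected), "/", nrow(x), "\n", sep = "")
  NextMethod()
}

#' @rdname tidy.prs_ols
#' @export
tidy.prs_selection <- function(x, ...) {
  out <- as_tibble(x)
  out$method <- attr(x, "method")
  out$threshold <- attr(x, "threshold")
  out$study_n <- attr(x, "study_n")
  out
}

#' Convert selection results to a 0/1 audit matrix
#'
#' @param selections A list of `prs_selection` objects over the same
#'   candidates.
#' @return An integer matrix, one row per selection, one column per
#'   candidate.
#' @export
selections_to_matrix <- function(selections) {
  check_selection_list(selections)
  vars <- selections[[1]]$variable
  out <- do.call(rbind, lapply(selections, function(s) {
    as.integer(s$selected)
  }))
  colnames(out) <- vars
  rownames(out) <- paste0("study", seq_along(selections))
  out
}

check_selection_list <- function(selections) {
  if (length(selections) == 0) abort("need at least one selection")
  if (!all(vapply(selections, inherits, logical(1), "prs_selection"))) {
    abort("all elements must be prs_selection objects")
  }
  vars <- selections[[1]]$variable
  same_vars <- vapply(selections, function(s) {
    identical(s$variable, vars)
  }, logical(1))
  if (!all(same_vars)) {
    abort("selections disagree on candidate names or order")
  }
  methods <- vapply(selections, attr, character(1), "method")
  if (length(unique(methods)) > 1) {
    abort("selections mix different methods")
  }
  invisible(selections)
}
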