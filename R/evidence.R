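# Combining selections across preceding studies into "background
# knowledge" under the k-of-n evidence rules.

#' Combine preceding-study selections into a known-predictor set
#'
#' A candidate becomes a "known" predictor when at least `m` of the
#' preceding studies selected it: rule 1 (`m = 1`, at least one study),
#' rule 2 (`m = 2`, at least two) and rule 3 (`m = 3`, all three).  The
#' module accepts any number of studies, but the emulated design uses
#' three.
#'
#' @param selections A list of `prs_selection` objects (same method, same
#'   candidate order), typically of length 3.
#' @param m Minimum number of selecting studies, `1 <= m <= length(selections)`.
#'
#' @return A `known_set` tibble with columns `variable`, `votes`, `known`
#'   and attributes `rule` (= `m`), `n_studies` and `method`.
#' @export
combine_evidence <- function(selections, m) {
  check_selection_list(selections)
  if (!(length(m) == 1 && m >= 1 && m <= length(selections) &&
        m == as.integer(m))) {
    abort("m must be an integer between 1 and the number of studies")
  }
  votes <- Reduce(`+`, lapply(selections, function(s) {
    as.integer(s$selected)
  }))
  new_known_set(
    tibble(variable = selections[[1]]$variable,
           votes = votes, known = votes >= m),
    rule = as.integer(m),
    n_studies = length(selections),
    method = attr(selections[[1]], "method")
  )
}

new_known_set <- function(tbl, rule, n_studies, method = NA_character_) {
  structure(tbl,
            class = c("known_set", class(tbl)),
            rule = rule, n_studies = n_studies, method = method)
}

# Build a known_set from a plain logical mask (internal fast path).
known_set_from_mask <- function(variables, mask, votes, rule,
                                n_studies = 3L, method = NA_character_) {
  new_known_set(tibble(variable = variables, votes = votes, known = mask),
                rule = rule, n_studies = n_studies, method = method)
}

#' @export
print.known_set <- function(x, ...) {
  cat("<known_set> rule ", attr(x, "rule"), " of ", attr(x, "n_studies"),
      " studies, ", sum(x$known), " known predictor(s)\n", sep = "")
  NextMethod()
}

#' @rdname tidy.prs_ols
#' @export
tidy.known_set <- function(x, ...) {
  out <- as_tibble(x)
  out$rule <- attr(x, "rule")
  out
}
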