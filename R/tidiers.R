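#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted strain forest
#'
#' One row per (strain, identified_as) pair with the identification rate
#' on the out-of-bag training confusion.
#'
#' @param x A `strain_forest`.
#' @param ... Unused.
#' @return A tibble: `strain`, `identified_as`, `rate`.
#' @export
tidy.strain_forest <- function(x, ...) {
  cm <- x$forest$confusion[, x$strains, drop = FALSE]
  rates <- prop.table(cm, margin = 1)
  out <- as.data.frame(as.table(rates), stringsAsFactors = FALSE)
  names(out) <- c("strain", "identified_as", "rate")
  tibble::as_tibble(out)
}

#' @rdname tidy.strain_forest
#' @export
glance.strain_forest <- function(x, ...) {
  cm <- x$forest$confusion[, x$strains, drop = FALSE]
  tibble::tibble(
    n_strains = length(x$strains), n_features = length(x$features),
    ntree = x$ntree, mtry = x$mtry, n_train = x$n_train,
    oob_accuracy = sum(diag(cm)) / sum(cm), seed = x$seed)
}

#' Tidy a mixture report
#'
#' @param x A `mixture_report`.
#' @param ... Unused.
#' @return The composition tibble (`strain`, `fraction`, `n`).
#' @export
tidy.mixture_report <- function(x, ...) x$composition

#' @rdname tidy.mixture_report
#' @export
glance.mixture_report <- function(x, ...) {
  tibble::tibble(n_objects = x$n_objects,
                 n_strains = nrow(x$composition),
                 qc = paste(x$qc, collapse = ";"))
}

#' Tidy an HPG pair result
#'
#' @param x An `hpg_result`.
#' @param ... Unused.
#' @return One-row tibble with the cutoff, counts, corrected viable count
#'   and the debiased viable-fraction estimate.
#' @export
tidy.hpg_result <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, n_A = x$n_A, n_A_v = x$n_A_v,
                 corrected_viable = x$corrected_viable,
                 viable_fraction_estimate = x$viable_fraction_estimate,
                 rule = x$rule)
}
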