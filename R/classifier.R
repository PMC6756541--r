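#' Columns never used as classifier features
#' @keywords internal
ID_COLUMNS <- c("plate", "well", "field", "label", "object_id", "strain",
                "partition", "qc_flags", "centroid_x", "centroid_y",
                "morphotype", "viable", "hpg_positive", "true_viable",
                "reason")

feature_columns <- function(table, features = NULL, exclude_roles = character(0)) {
  if (!is.null(features)) {
    miss <- setdiff(features, names(table))
    if (length(miss))
      stop_hca("feature column(s) missing: %s", paste(miss, collapse = ", "))
    return(features)
  }
  cand <- setdiff(names(table), ID_COLUMNS)
  cand <- cand[vapply(table[cand], is.numeric, TRUE)]
  for (role in exclude_roles)
    cand <- cand[!grepl(paste0("_", role, "$"), cand)]
  if (!length(cand)) stop_hca("no usable feature columns found")
  cand
}

#' Stratified train/test/validation partition
#'
#' Splits a labelled per-object table into disjoint train/test/validation
#' partitions (default 60%/20%/20%), stratified by strain and reproducible
#' per seed. Fails if any stratum holds fewer than 5 objects.
#'
#' @param table Per-object tibble with a `strain` column.
#' @param fractions Named or positional fractions summing to 1.
#' @param seed Integer seed.
#' @param strain_col Stratification column (default `"strain"`).
#' @return The table with an added `partition` factor column
#'   (`train`/`test`/`validation`).
#' @export
partition_objects <- function(table, fractions = c(train = 0.6, test = 0.2,
                                                   validation = 0.2),
                              seed = 1L, strain_col = "strain") {
  stopifnot(is.data.frame(table), strain_col %in% names(table))
  if (abs(sum(fractions) - 1) > 1e-9) stop_hca("fractions must sum to 1")
  if (is.null(names(fractions))) names(fractions) <- c("train", "test", "validation")
  sizes <- table(table[[strain_col]])
  if (any(sizes < 5))
    stop_hca("stratum '%s' has fewer than 5 objects (%d)",
             names(sizes)[which.min(sizes)], min(sizes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  part <- character(nrow(table))
  for (s in names(sizes)) {
    idx <- which(table[[strain_col]] == s)
    n <- length(idx)
    # largest-remainder apportionment of n across the three partitions
    target <- fractions * n
    base <- floor(target)
    rem <- n - sum(base)
    if (rem > 0) {
      order_rem <- order(target - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    }
    part[sample(idx)] <- rep(names(fractions), times = base)
  }
  out <- table
  out$partition <- factor(part, levels = names(fractions))
  out
}

#' Train a bootstrap random forest on pure-culture objects
#'
#' Reference configuration: 100 bootstrap trees, `floor(sqrt(p))` candidate
#' features per split, unlimited depth, bootstrap size equal to the
#' training size; prediction is the majority vote over trees, with ties
#' broken toward the lexicographically lowest strain label for
#' determinism. Features default to every numeric morphometry/intensity
#' column, excluding identifiers, QC flags and truth columns.
#'
#' @param train Training tibble (e.g. the `partition == "train"` rows of
#'   [partition_objects()]) with a `strain` column.
#' @param features Explicit feature columns (default: auto-selected).
#' @param exclude_roles Channel roles whose intensity features are dropped
#'   (e.g. the gating channel when it would leak treatment).
#' @param seed Integer seed.
#' @param ntree,mtry,nodesize Forest parameters (defaults 100,
#'   `floor(sqrt(p))`, 1).
#' @return A `strain_forest` object wrapping the fitted forest with its
#'   feature schema and seed.
#' @export
train_strain_forest <- function(train, features = NULL,
                                exclude_roles = character(0), seed = 1L,
                                ntree = 100, mtry = NULL, nodesize = 1) {
  stopifnot(is.data.frame(train), "strain" %in% names(train))
  strains <- sort(unique(train$strain))
  if (length(strains) < 2) stop_hca("need >= 2 strains to train")
  feats <- feature_columns(train, features, exclude_roles)
  x <- as.data.frame(train[feats])
  if (!all(vapply(x, function(v) all(is.finite(v)), TRUE)))
    stop_hca("features must be finite")
  if (all(vapply(x, function(v) length(unique(v)) == 1, TRUE)))
    stop_hca("all features are constant; nothing to learn")
  y <- factor(train$strain, levels = strains)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(feats))))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                                   nodesize = nodesize,
                                   sampsize = nrow(x), replace = TRUE)
  structure(list(forest = rf, features = feats, strains = strains,
                 seed = seed, ntree = ntree, mtry = mtry,
                 n_train = nrow(x)),
            class = "strain_forest")
}

#' @export
print.strain_forest <- function(x, ...) {
  cat(sprintf("<strain_forest> %d strains (%s), %d trees, %d features, trained on %d objects\n",
              length(x$strains), paste(x$strains, collapse = ", "),
              x$ntree, length(x$features), x$n_train))
  invisible(x)
}

#' Predict strain labels with deterministic tie-breaking
#'
#' @param object A `strain_forest`.
#' @param newdata Per-object tibble carrying the training feature columns.
#' @param ... Unused.
#' @return Tibble with `strain_predicted` and `vote_fraction` (fraction of
#'   trees voting for the winning strain).
#' @export
predict.strain_forest <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop_hca("feature schema mismatch; missing column(s): %s",
             paste(miss, collapse = ", "))
  x <- as.data.frame(newdata[object$features])
  votes <- predict(object$forest, x, type = "vote", norm.votes = TRUE)
  votes <- votes[, object$strains, drop = FALSE]
  win <- apply(votes, 1, which.max)  # first max = lexicographically lowest
  tibble::tibble(
    strain_predicted = object$strains[win],
    vote_fraction = votes[cbind(seq_len(nrow(votes)), win)])
}

#' Per-strain identification rates on full single-strain datasets
#'
#' Applies the model to all objects of each strain and reports the
#' confusion as rates: the diagonal is the positive identification rate,
#' off-diagonals are false identification rates toward each other strain.
#' Each row sums to 1.
#'
#' @param model A `strain_forest`.
#' @param data Per-object tibble with the true `strain` column, covering
#'   every modelled strain.
#' @return Tibble in long form: `strain`, `identified_as`, `rate`, `n`.
#' @export
evaluate_per_strain <- function(model, data) {
  stopifnot("strain" %in% names(data))
  pred <- predict(model, data)
  tab <- table(factor(data$strain, levels = model$strains),
               factor(pred$strain_predicted, levels = model$strains))
  rates <- prop.table(tab, margin = 1)
  out <- as.data.frame(rates, stringsAsFactors = FALSE)
  names(out) <- c("strain", "identified_as", "rate")
  out$n <- as.integer(rowSums(tab))[match(out$strain, rownames(tab))]
  tibble::as_tibble(out)
}

#' Classify a mixed culture and estimate its composition
#'
#' Every object receives its most probable strain; composition is the
#' frequency of assigned labels.
#'
#' @param model A `strain_forest`.
#' @param records Per-object tibble of the mixed culture.
#' @return A `mixture_report`: `objects` (per-object label and vote
#'   fraction), `composition` (tibble `strain`, `fraction`, `n`), `n_objects`,
#'   `qc` flags (`"empty_input"` when no objects).
#' @export
classify_mixture <- function(model, records) {
  if (nrow(records) == 0) {
    return(structure(list(
      objects = tibble::tibble(strain_predicted = character(0),
                               vote_fraction = numeric(0)),
      composition = tibble::tibble(strain = model$strains,
                                   fraction = rep(NA_real_, length(model$strains)),
                                   n = 0L),
      n_objects = 0L, qc = "empty_input"), class = "mixture_report"))
  }
  pred <- predict(model, records)
  comp <- table(factor(pred$strain_predicted, levels = model$strains))
  structure(list(
    objects = dplyr::bind_cols(records, pred),
    composition = tibble::tibble(strain = names(comp),
                                 fraction = as.numeric(comp) / nrow(records),
                                 n = as.integer(comp)),
    n_objects = nrow(records), qc = character(0)),
    class = "mixture_report")
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf("<mixture_report> %d objects\n", x$n_objects))
  if (x$n_objects > 0)
    print(x$composition)
  invisible(x)
}
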