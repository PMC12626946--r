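#' Complex-level blind hold-out split
#'
#' Splits a dataset at the antibody-antigen complex level so both chains
#' of a complex always land on the same side. The blind set holds
#' `round(n * blind_fraction)` complexes, selected seeded-randomly, and is
#' withheld from all training and tuning.
#'
#' @param ds A `labeled_dataset` with at least 2 complexes.
#' @param blind_fraction Fraction of complexes to hold out, in (0, 1).
#' @param seed Integer seed; the split is a pure function of
#'   (dataset ids, fraction, seed).
#' @return List with `modeling` and `blind` `labeled_dataset`s.
#' @export
split_blind <- function(ds, blind_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (length(ds$complexes) < 2L) stop("need at least 2 complexes to split")
  if (blind_fraction <= 0 || blind_fraction >= 1) {
    stop("blind_fraction must be in (0, 1)")
  }
  n <- length(ds$complexes)
  n_blind <- round(n * blind_fraction)
  set.seed(seed)
  blind_idx <- sort(sample.int(n, n_blind))
  list(
    modeling = labeled_dataset(ds$complexes[setdiff(seq_len(n), blind_idx)],
                               provenance = c(ds$provenance, "modeling split")),
    blind = labeled_dataset(ds$complexes[blind_idx],
                            provenance = c(ds$provenance, "blind split"))
  )
}

#' Stratified grouped k-fold plan over complexes
#'
#' Builds `k` folds of complexes balanced in size (within 1) and
#' stratified by the quartile-binned per-complex binding-residue fraction,
#' so the class balance the imbalance-sensitive metrics depend on is
#' similar across folds. Both chains of a complex are always in the same
#' fold (grouping), which prevents information leakage between the
#' training and validation sides.
#'
#' @param modeling A `labeled_dataset` (the modeling split).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the fold assignment is a pure function of
#'   (dataset ids, k, seed).
#' @param blind Optional character vector of blind complex ids, recorded
#'   in the plan for leakage auditing.
#' @return A `split_plan` with fields `folds` (list of k disjoint id sets
#'   covering the modeling ids), `blind`, `seed`, `stratification`.
#' @export
make_folds <- function(modeling, k = 5L, seed = 1L, blind = character()) {
  stopifnot(inherits(modeling, "labeled_dataset"), k >= 2L)
  ids <- complex_ids(modeling)
  n <- length(ids)
  if (n < k) stop("need at least k = ", k, " complexes, got ", n)
  frac <- vapply(modeling$complexes, function(cx) {
    (sum(cx$heavy$labels) + sum(cx$light$labels)) /
      (chain_length(cx$heavy) + chain_length(cx$light))
  }, numeric(1))
  breaks <- unique(stats::quantile(frac, probs = seq(0, 1, 0.25)))
  bins <- if (length(breaks) > 2L) {
    cut(frac, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, n)
  set.seed(seed)
  fold_of <- integer(n)
  counter <- 0L
  for (b in sort(unique(bins))) {
    members <- which(bins == b)
    members <- members[sample.int(length(members))]
    # deal round-robin, continuing the fold pointer across bins so total
    # fold sizes stay within +/- 1
    fold_of[members] <- (counter + seq_along(members) - 1L) %% k + 1L
    counter <- counter + length(members)
  }
  plan <- structure(
    list(folds = lapply(seq_len(k), function(f) ids[fold_of == f]),
         blind = as.character(blind), seed = as.integer(seed),
         stratification = "quartile-binned per-complex binding fraction"),
    class = "split_plan"
  )
  validate_split_plan(plan, modeling_ids = ids)
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, length, integer(1))
  cat(sprintf("<split_plan> %d folds (sizes %s), %d blind complexes, seed %d\n",
              length(x$folds), paste(sizes, collapse = "/"), length(x$blind), x$seed))
  invisible(x)
}

# invariants: folds disjoint, cover the modeling ids, no blind overlap
validate_split_plan <- function(plan, modeling_ids = NULL) {
  all_fold <- unlist(plan$folds)
  if (anyDuplicated(all_fold)) stop("split plan has a complex in two folds")
  if (length(intersect(all_fold, plan$blind)) > 0L) {
    stop("split plan has a complex in both the folds and the blind set")
  }
  if (!is.null(modeling_ids) && !setequal(all_fold, modeling_ids)) {
    stop("folds do not cover the modeling set exactly")
  }
  invisible(plan)
}

#' Training/validation complex ids for one cross-validation fold
#'
#' Fold `fold` is the validation side; the remaining folds train.
#'
#' @param plan A `split_plan`.
#' @param fold Fold index in `1..k`.
#' @return List with `train` and `val` character id vectors.
#' @export
fold_ids <- function(plan, fold) {
  stopifnot(inherits(plan, "split_plan"), fold >= 1L, fold <= length(plan$folds))
  list(train = unlist(plan$folds[-fold]), val = plan$folds[[fold]])
}

#' Select chains for a chain-training regime
#'
#' `"H"` returns heavy chains only, `"L"` light chains only, `"HL"` both
#' chains of every complex as independent examples (chains are pooled,
#' never concatenated per antibody).
#'
#' @param ds A `labeled_dataset` (or list of `antibody_complex`).
#' @param regime `"H"`, `"L"` or `"HL"`.
#' @return List of `labeled_chain` objects.
#' @export
select_chain_regime <- function(ds, regime = c("HL", "H", "L")) {
  regime <- match.arg(regime)
  complexes <- if (inherits(ds, "labeled_dataset")) ds$complexes else ds
  switch(regime,
         H = lapply(complexes, `[[`, "heavy"),
         L = lapply(complexes, `[[`, "light"),
         HL = all_chains(labeled_dataset(complexes)))
}

#' Subset a dataset to a set of complex ids, preserving order
#'
#' @param ds A `labeled_dataset`.
#' @param ids Character vector of complex ids to keep.
#' @return A `labeled_dataset` with the matching complexes.
#' @export
subset_dataset <- function(ds, ids) {
  keep <- complex_ids(ds) %in% ids
  labeled_dataset(ds$complexes[keep], provenance = ds$provenance)
}

#' Write / read a split plan as a plain-text id-list file
#'
#' Serialization lets a split be frozen, shared and replayed exactly. The
#' format is a TSV with columns `set` (`blind` or `fold<k>`) and
#' `complex_id`, preceded by `# seed:` and `# stratification:` comment
#' lines.
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @return `path` invisibly (`write_split_plan`); a `split_plan`
#'   (`read_split_plan`).
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", plan$seed),
               sprintf("# stratification: %s", plan$stratification),
               "set\tcomplex_id"), con)
  for (f in seq_along(plan$folds)) {
    if (length(plan$folds[[f]]))
      writeLines(sprintf("fold%d\t%s", f, plan$folds[[f]]), con)
  }
  if (length(plan$blind)) writeLines(sprintf("blind\t%s", plan$blind), con)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  lines <- readLines(path)
  seed <- as.integer(sub("^# seed: ", "", lines[grepl("^# seed:", lines)][1]))
  strat <- sub("^# stratification: ", "", lines[grepl("^# stratification:", lines)][1])
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  fold_names <- sort(unique(tab$set[grepl("^fold", tab$set)]))
  k <- length(fold_names)
  plan <- structure(
    list(folds = lapply(seq_len(k), function(f) tab$complex_id[tab$set == paste0("fold", f)]),
         blind = tab$complex_id[tab$set == "blind"],
         seed = seed, stratification = strat),
    class = "split_plan"
  )
  validate_split_plan(plan)
  plan
}
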