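#' @title Imbalanced dataset construction by random-grouping undersampling
#' @description
#' Tools for manufacturing class-imbalanced detection datasets from an
#' approximately balanced one: the categories are randomly partitioned
#' into three groups of three, each group slot is assigned a retention
#' proportion, and every category is undersampled (uniformly, without
#' replacement, seeded) to `round(proportion * count)` of its samples.
#' Share and max:min ratio statistics summarize the resulting imbalance.
#'
#' A reference construction for a nine-category tomato leaf disease
#' corpus ships with the package (three experiments of increasing
#' imbalance; see [imbalance_reference()]), together with the per-category
#' image counts of the balanced source corpus ([tomato_categories()]).
#' @name imbalance
NULL

# seeded evaluation that never disturbs the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round half away from zero (commercial rounding); base round() rounds
# half to even, which is not what sample-count arithmetic expects
round_half_up <- function(x) floor(x + 0.5)

#' Create a per-category dataset index
#'
#' @param samples named list: one element per category (name = category
#'   id) holding a vector of unique sample ids.
#' @return object of class `dataset_index`.
#' @export
dataset_index <- function(samples) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list keyed by category id")
  all_ids <- unlist(samples, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("sample ids must be unique across categories")
  structure(list(samples = samples), class = "dataset_index")
}

#' Per-category counts of an index
#' @param index a [dataset_index()].
#' @return named integer vector.
#' @export
index_counts <- function(index) {
  vapply(index$samples, length, integer(1))
}

#' @export
print.dataset_index <- function(x, ...) {
  cnt <- index_counts(x)
  cat("<dataset_index> ", length(cnt), " categories, ",
      sum(cnt), " samples\n", sep = "")
  print(cnt)
  invisible(x)
}

#' Randomly partition categories into three groups of three
#'
#' @param category_ids vector of exactly nine category ids.
#' @param seed integer seed; the partition is deterministic per seed.
#' @return list of three vectors of three ids.
#' @export
random_group_partition <- function(category_ids, seed) {
  if (length(category_ids) != 9L)
    stop("random grouping requires exactly 9 categories, got ",
         length(category_ids))
  perm <- with_seed(seed, sample(category_ids))
  list(perm[1:3], perm[4:6], perm[7:9])
}

#' Specify an undersampling plan
#'
#' @param groups list of three disjoint vectors of three category ids
#'   covering all nine categories.
#' @param proportions list of three numeric vectors of three retention
#'   fractions in `(0, 1]`, assigned to the group's categories in order.
#' @param seed integer seed for the sample draws.
#' @return object of class `imbalance_spec`.
#' @export
imbalance_spec <- function(groups, proportions, seed) {
  ids <- unlist(groups)
  if (length(groups) != 3L || any(lengths(groups) != 3L) ||
      anyDuplicated(ids))
    stop("groups must be 3 disjoint sets of 3 category ids")
  if (length(proportions) != 3L || any(lengths(proportions) != 3L))
    stop("proportions must be 3 vectors of 3 fractions")
  p <- unlist(proportions)
  if (any(p <= 0 | p > 1)) stop("proportions must lie in (0, 1]")
  structure(list(groups = groups, proportions = proportions,
                 seed = as.integer(seed)),
            class = "imbalance_spec")
}

#' Undersample an index according to an imbalance plan
#'
#' For category `c` in group `g` at slot `s`, retains
#' `round(proportion[g][s] * count(c))` samples (round half up), drawn
#' uniformly without replacement under the plan's seed.
#'
#' @param index a [dataset_index()].
#' @param spec an [imbalance_spec()]; every category in the plan must be
#'   present and non-empty in the index.
#' @return the undersampled [dataset_index()].
#' @export
apply_proportions <- function(index, spec) {
  stopifnot(inherits(index, "dataset_index"),
            inherits(spec, "imbalance_spec"))
  out <- index$samples
  with_seed(spec$seed, {
    for (g in seq_along(spec$groups)) {
      for (s in seq_along(spec$groups[[g]])) {
        cat_id <- as.character(spec$groups[[g]][[s]])
        p <- spec$proportions[[g]][[s]]
        ids <- index$samples[[cat_id]]
        if (is.null(ids) || length(ids) == 0L)
          stop("category ", cat_id, " is empty or absent from the index")
        keep <- round_half_up(p * length(ids))
        out[[cat_id]] <- sort(sample(ids, keep))
      }
    }
  })
  dataset_index(out)
}

#' Share and ratio statistics of a dataset index
#'
#' Shares are percentages of the total, reported rounded to one decimal;
#' the imbalance ratio is the rounded maximum share divided by the
#' rounded minimum share — the convention used when quoting ratios such
#' as "11.9 : 1 (23.8% : 2.0%)".
#'
#' @param index a [dataset_index()], or a named vector of per-category
#'   counts.
#' @return list with `counts`, `total`, `share` (exact, %), `share_rounded`
#'   (one decimal, %), `max_share`, `min_share`, `ratio`.
#' @export
imbalance_stats <- function(index) {
  cnt <- if (inherits(index, "dataset_index")) index_counts(index)
         else index
  total <- sum(cnt)
  if (total <= 0) stop("index is empty")
  share <- cnt / total * 100
  sr <- round(share, 1)
  list(counts = cnt, total = total, share = share, share_rounded = sr,
       max_share = max(sr), min_share = min(sr),
       ratio = max(sr) / min(sr))
}

#' Stratified train/test split of an index
#'
#' Splits every category independently: `round(test_fraction * count)`
#' samples go to the test index, the remainder to the train index, drawn
#' uniformly under the seed. No id appears in both outputs.
#'
#' @param index a [dataset_index()].
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` [dataset_index()] objects.
#' @export
stratified_split <- function(index, test_fraction, seed) {
  stopifnot(inherits(index, "dataset_index"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  train <- test <- index$samples
  with_seed(seed, {
    for (cat_id in names(index$samples)) {
      ids <- index$samples[[cat_id]]
      n_test <- round_half_up(test_fraction * length(ids))
      te <- sort(sample(ids, n_test))
      test[[cat_id]] <- te
      train[[cat_id]] <- setdiff(ids, te)
    }
  })
  list(train = dataset_index(train), test = dataset_index(test))
}

#' Reference imbalanced-dataset constructions
#'
#' Three undersampling experiments of increasing imbalance for a
#' nine-category tomato leaf disease corpus: the random grouping of the
#' categories, the retention proportion of each group slot, and the
#' per-category quantity retained. These quantities are carried as a
#' fixture (the balanced pool they were drawn from is not distributed
#' with the package) and drive the share/ratio statistics used in the
#' examples and tests.
#'
#' @return data frame with columns `experiment`, `group`, `slot`,
#'   `category`, `proportion`, `quantity`.
#' @export
imbalance_reference <- function() {
  utils::read.csv(system.file("extdata", "imbalance_reference.csv",
                              package = "msfdet"))
}

#' Category table of the balanced tomato leaf disease corpus
#'
#' Nine disease categories (including healthy) with per-category image
#' counts of the laboratory-background and field-background collections.
#'
#' @return data frame with columns `category`, `name`, `lab_count`,
#'   `env_count`.
#' @export
tomato_categories <- function() {
  utils::read.csv(system.file("extdata", "tomato_categories.csv",
                              package = "msfdet"))
}
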