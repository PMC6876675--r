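# Composite nutrition and food-security indicators built from raw survey
# instruments: inverse-probability-weighted knowledge exam scores, dietary
# diversity counts under several food-group schemes, the food consumption
# score (FCS, HKI/WFP protocol), vitamin A consumption frequency, and
# food-security measures (MIHFP, relief months, asset sales, coping index).

# Food group map ---------------------------------------------------------------

#' Load a food-group mapping scheme
#'
#' The map relates the 12 survey food categories to the groups of five
#' scoring schemes: 8-group household dietary diversity (HDDS), 8-group child
#' dietary diversity (organ meat separate; vitamin-A-rich vs other fruits and
#' vegetables distinguished; oil excluded), 10-group food-group diversity
#' (FGDS), 6-group vitamin A diversity, and the 7-group food consumption
#' score with its weights. The default map and weight vector ship as editable
#' CSV files under `extdata`; the FCS weights follow the standard WFP/HKI
#' vector (staples 2, pulses 3, vegetables 1, fruit 1, meat/fish 4, milk 4,
#' oil merged with sugar 0.5).
#'
#' @param path,weights_path Optional paths to a custom map / FCS weight CSV;
#'   defaults to the files shipped with the package.
#' @return Object of class `"food_group_map"`: list with `map` (data frame
#'   with columns `category`, `hdds`, `cdds`, `fgds`, `vita`, `fcs`) and
#'   `fcs_weights` (named numeric vector).
#' @export
food_group_map <- function(path = NULL, weights_path = NULL) {
  path <- path %||% system.file("extdata", "food_groups.csv",
                                package = "ipwdid", mustWork = TRUE)
  weights_path <- weights_path %||% system.file("extdata", "fcs_weights.csv",
                                                package = "ipwdid",
                                                mustWork = TRUE)
  map <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "hdds", "cdds", "fgds", "vita", "fcs")
  missing <- setdiff(need, names(map))
  if (length(missing))
    ipw_stop("food group map missing columns: ",
             paste(missing, collapse = ", "))
  w <- read.csv(weights_path, stringsAsFactors = FALSE)
  if (!all(c("group", "weight") %in% names(w)))
    ipw_stop("FCS weight file needs columns group, weight")
  if (any(w$weight <= 0)) ipw_stop("FCS weights must be positive")
  used <- setdiff(unique(map$fcs), "")
  missing_w <- setdiff(used, w$group)
  if (length(missing_w))
    ipw_stop("FCS groups without weight: ", paste(missing_w, collapse = ", "))
  structure(list(map = map, fcs_weights = setNames(w$weight, w$group)),
            class = "food_group_map")
}

scheme_bounds <- c(hdds = 8, cdds = 8, fgds = 10, vita = 6)

as_category_matrix <- function(x, map, what) {
  ncat <- nrow(map$map)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncat)
    ipw_stop(what, " needs ", ncat, " category columns, got ", ncol(x))
  if (!is.null(colnames(x)) && all(map$map$category %in% colnames(x)))
    x <- x[, map$map$category, drop = FALSE]
  x
}

diversity_count <- function(recall, map, scheme) {
  recall <- as_category_matrix(recall, map, "24-hour recall")
  if (!all(recall %in% c(0, 1)))
    ipw_stop("recall indicators must be 0/1")
  groups <- map$map[[scheme]]
  keep <- groups != ""
  g <- factor(groups[keep])
  # count groups in which at least one mapped category was consumed
  agg <- recall[, keep, drop = FALSE] %*%
    outer(as.integer(g), seq_len(nlevels(g)), "==")
  as.integer(rowSums(agg > 0))
}

#' Dietary diversity scores from 24-hour recall
#'
#' Each score counts, under its scheme's category-to-group mapping, the
#' groups from which at least one food category was consumed during the
#' previous 24 hours: `hdds()` over 8 household groups, `cdds()` over 8 child
#' groups, `fgds()` over 10 groups, `vita_diversity()` over the 6 groups that
#' are sources of vitamin A or beta-carotene.
#'
#' @param recall Vector of 12 binary category indicators, or a matrix/data
#'   frame with one row per observation (columns in map order, or named by
#'   category).
#' @param map A [food_group_map()].
#' @return Integer vector of counts (bounds 0-8, 0-8, 0-10, 0-6).
#' @export
hdds <- function(recall, map = food_group_map())
  diversity_count(recall, map, "hdds")

#' @rdname hdds
#' @export
cdds <- function(recall, map = food_group_map())
  diversity_count(recall, map, "cdds")

#' @rdname hdds
#' @export
fgds <- function(recall, map = food_group_map())
  diversity_count(recall, map, "fgds")

#' @rdname hdds
#' @export
vita_diversity <- function(recall, map = food_group_map())
  diversity_count(recall, map, "vita")

#' Food consumption score from 7-day food-group frequencies
#'
#' Item frequencies (days consumed in the last 7) are summed within each FCS
#' group, each group total is capped at 7, multiplied by the group weight,
#' and the weighted group scores are summed.
#'
#' @param freq Vector of per-category day counts in `[0, 7]`, or matrix/data
#'   frame with one row per observation.
#' @param map A [food_group_map()].
#' @return Numeric vector of scores.
#' @export
fcs <- function(freq, map = food_group_map()) {
  freq <- as_category_matrix(freq, map, "7-day frequency")
  if (any(freq < 0)) ipw_stop("frequencies must be non-negative")
  groups <- map$map$fcs
  keep <- groups != ""
  g <- factor(groups[keep])
  sums <- freq[, keep, drop = FALSE] %*%
    outer(as.integer(g), seq_len(nlevels(g)), "==")
  capped <- pmin(sums, 7)
  w <- map$fcs_weights[levels(g)]
  as.numeric(capped %*% w)
}

#' Frequency of vitamin A-rich food consumption (days per week)
#'
#' Day counts of the vitamin A-rich items are summed and capped at 7 (the
#' instrument does not record which days overlap, so the union of day sets is
#' resolved as `min(sum of item days, 7)`).
#'
#' @param freq As in [fcs()].
#' @param map A [food_group_map()]; the vitamin A items are the categories
#'   with a non-empty `vita` group.
#' @return Numeric vector of days in `[0, 7]`.
#' @export
vita_freq <- function(freq, map = food_group_map()) {
  freq <- as_category_matrix(freq, map, "7-day frequency")
  if (any(freq < 0)) ipw_stop("frequencies must be non-negative")
  keep <- map$map$vita != ""
  pmin(rowSums(freq[, keep, drop = FALSE]), 7)
}

# Knowledge scores --------------------------------------------------------------

#' Fit inverse-probability knowledge-exam item weights
#'
#' The weight of each exam item is the inverse of the fraction of the
#' reference sample answering it correctly, so harder questions (answered
#' correctly by few) carry more weight. Items never answered correctly in the
#' reference sample cannot be weighted and are excluded with a warning.
#'
#' @param responses Binary item-response matrix (rows = respondents, columns
#'   = items; column names identify items).
#' @param reference Logical or integer row selector defining the reference
#'   sample (default: all rows). The package convention is to fit on the
#'   pooled baseline sample and hold weights fixed across waves.
#' @return Object of class `"knowledge_weights"`: list with `p_correct`,
#'   `weights` (both named per item), `excluded`, `n_reference`.
#' @export
fit_knowledge_weights <- function(responses, reference = NULL) {
  responses <- as.matrix(responses)
  if (!all(responses %in% c(0, 1, NA)))
    ipw_stop("exam responses must be binary")
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("item_%02d", seq_len(ncol(responses)))
  ref <- if (is.null(reference)) responses
         else responses[reference, , drop = FALSE]
  if (nrow(ref) == 0) ipw_stop("reference sample is empty")
  p <- colMeans(ref, na.rm = TRUE)
  excluded <- names(p)[p == 0 | is.nan(p)]
  if (length(excluded))
    warning("items never answered correctly in reference sample, excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  keep <- setdiff(names(p), excluded)
  structure(list(p_correct = p[keep], weights = 1 / p[keep],
                 excluded = excluded, n_reference = nrow(ref)),
            class = "knowledge_weights")
}

#' Weighted knowledge score
#'
#' Sum of correct responses weighted by the inverse probability of a correct
#' answer in the reference sample. Disjoint production and vitamin A item
#' subsets make the combined score (over their union) the exact sum of the
#' two subscores.
#'
#' @param responses Binary response matrix or vector (named by item).
#' @param weights A [fit_knowledge_weights()] object.
#' @param items Character subset of weighted items (default: all).
#' @param missing Policy for `NA` responses: `"incorrect"` (default, scored
#'   0) or `"error"`.
#' @return Numeric score vector, in score points.
#' @export
knowledge_score <- function(responses, weights, items = NULL,
                            missing = c("incorrect", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(weights, "knowledge_weights"))
  if (is.null(dim(responses)))
    responses <- matrix(responses, nrow = 1,
                        dimnames = list(NULL, names(responses)))
  responses <- as.matrix(responses)
  items <- items %||% names(weights$weights)
  bad <- setdiff(items, names(weights$weights))
  if (length(bad))
    ipw_stop("items without fitted weight: ", paste(bad, collapse = ", "))
  r <- responses[, items, drop = FALSE]
  if (anyNA(r)) {
    if (missing == "error") ipw_stop("missing exam responses")
    r[is.na(r)] <- 0
  }
  as.numeric(r %*% weights$weights[items])
}

#' Standardize a score against a reference sample
#'
#' Returns `(x - mean(reference)) / sd(reference)`, the standardized index in
#' SD units; the reference mean and SD are attached as attributes.
#'
#' @param x Numeric vector to standardize.
#' @param reference Numeric reference sample (default `x` itself).
#' @return Numeric vector with attributes `ref_mean`, `ref_sd`.
#' @export
standardize <- function(x, reference = x) {
  m <- mean(reference)
  s <- sd(reference)
  if (!is.finite(s) || s == 0)
    ipw_stop("reference standard deviation is zero; cannot standardize")
  structure((x - m) / s, ref_mean = m, ref_sd = s)
}

# Food security ------------------------------------------------------------------

#' Food-security indicators from month calendars and coping responses
#'
#' @param months_low_food Matrix/vector of 12 binary month flags: fewer than
#'   two meals a day from own resources (MIHFP).
#' @param months_relief 12 binary month flags: received relief food.
#' @param sold_asset 0/1: sold an asset to buy food.
#' @param strategies_count Non-negative count of coping strategies employed
#'   (the aggregate food-insecurity index; passed through with a range
#'   check).
#' @return Data frame with columns `mihfp`, `relief_months`, `sold_asset`,
#'   `food_insecurity_score`.
#' @export
food_security <- function(months_low_food, months_relief, sold_asset,
                          strategies_count) {
  as12 <- function(x, what) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- as.matrix(x)
    if (ncol(x) != 12)
      ipw_stop(what, " must have exactly 12 month flags, got ", ncol(x))
    if (!all(x %in% c(0, 1))) ipw_stop(what, " flags must be 0/1")
    x
  }
  ml <- as12(months_low_food, "months_low_food")
  mr <- as12(months_relief, "months_relief")
  if (!all(sold_asset %in% c(0, 1))) ipw_stop("sold_asset must be 0/1")
  if (any(strategies_count < 0))
    ipw_stop("strategies_count must be non-negative")
  data.frame(mihfp = as.integer(rowSums(ml)),
             relief_months = as.integer(rowSums(mr)),
             sold_asset = as.integer(sold_asset),
             food_insecurity_score = as.numeric(strategies_count))
}

# Panel-level indicator table -----------------------------------------------------

#' Build the indicator table for a panel
#'
#' Computes every composite indicator for each household x wave from the raw
#' instrument columns: inverse-probability-weighted knowledge scores
#' (production, vitamin A, combined; weights fit on the pooled baseline
#' sample and held fixed across waves) with standardized variants
#' (standardized against the baseline sample), the four dietary diversity
#' counts, FCS, vitamin A consumption frequency, and the food-security
#' indicators.
#'
#' @param panel A `"household_panel"` with instrument columns.
#' @param map A [food_group_map()].
#' @return Data frame keyed by `household_id` and `wave`.
#' @export
indicator_table <- function(panel, map = food_group_map()) {
  stopifnot(inherits(panel, "household_panel"))
  d <- panel$data
  need <- c(panel$exam_items$production, panel$exam_items$vitamina)
  if (is.null(need) || !all(need %in% names(d)))
    ipw_stop("panel has no instrument columns; generate with instruments ",
             "= TRUE or supply a full panel CSV")
  prod_items <- panel$exam_items$production
  vita_items <- panel$exam_items$vitamina
  exam <- as.matrix(d[, c(prod_items, vita_items)])
  w <- fit_knowledge_weights(exam, reference = d$wave == 0)
  kp <- knowledge_score(exam, w, intersect(prod_items, names(w$weights)))
  kv <- knowledge_score(exam, w, intersect(vita_items, names(w$weights)))
  kc <- kp + kv

  base <- d$wave == 0
  recall <- d[, grep("^recall_g", names(d)), drop = FALSE]
  freq <- d[, grep("^freq_f", names(d)), drop = FALSE]
  fsec <- food_security(d[, grep("^month_low_", names(d))],
                        d[, grep("^month_relief_", names(d))],
                        d$sold_asset, d$strategies_count)
  out <- data.frame(
    household_id = d$household_id, wave = d$wave,
    knowledge_production = kp, knowledge_vitamina = kv,
    knowledge_combined = kc,
    knowledge_production_std = as.numeric(standardize(kp, kp[base])),
    knowledge_vitamina_std = as.numeric(standardize(kv, kv[base])),
    knowledge_combined_std = as.numeric(standardize(kc, kc[base])),
    hdds = hdds(recall, map), cdds = cdds(recall, map),
    fgds = fgds(recall, map), vita_diversity = vita_diversity(recall, map),
    fcs = fcs(freq, map), vita_freq_days = vita_freq(freq, map))
  cbind(out, fsec)
}
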