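# Shared fixtures: a fast small DGP configuration and hand-built panels with
# known closed-form DID structure.

small_config <- function(seed = 1, ...) {
  dgp_config(n_households = 120, n_villages = 8, seed = seed, ...)
}

# Panel with specified cell means (T0, T1, C0, C1) plus optional per-cell
# noise; villages assigned round-robin. Closed-form DID = (T1-T0) - (C1-C0).
toy_panel <- function(n_treated = 6, n_control = 6, cells = c(1, 4, 2, 3),
                      n_villages = 4, noise = 0, seed = 1,
                      extra_outcomes = list()) {
  set.seed(seed)
  n <- n_treated + n_control
  treated <- rep(c(1L, 0L), c(n_treated, n_control))
  village <- rep_len(seq_len(n_villages), n)
  mk <- function(wave) {
    mu <- ifelse(treated == 1,
                 if (wave == 0) cells[1] else cells[2],
                 if (wave == 0) cells[3] else cells[4])
    data.frame(household_id = seq_len(n), village_id = village,
               wave = wave, treated = treated,
               y = mu + rnorm(n, 0, noise))
  }
  data <- rbind(mk(0), mk(1))
  for (nm in names(extra_outcomes)) data[[nm]] <- extra_outcomes[[nm]]
  data <- data[order(data$household_id, data$wave), ]
  rownames(data) <- NULL
  structure(list(data = data,
                 covariates = data.frame(name = character(),
                                         kind = character()),
                 outcome_names = c("y", names(extra_outcomes)),
                 exam_items = NULL, n_households = n,
                 n_villages = n_villages, config = NULL),
            class = "household_panel")
}

# A 12-category recall vector with the given categories set to 1, in the
# default map's category order.
recall_vec <- function(on = character()) {
  m <- food_group_map()
  setNames(as.integer(m$map$category %in% on), m$map$category)
}

freq_vec <- function(values = list()) {
  m <- food_group_map()
  v <- setNames(rep(0, nrow(m$map)), m$map$category)
  for (nm in names(values)) v[nm] <- values[[nm]]
  v
}
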