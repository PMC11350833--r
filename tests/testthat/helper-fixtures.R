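# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(10, 0, 25, 3,
                12, 1, 20, 0,
                 9, 9, 9, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("h1", "h2", "h3"),
                              c("otu1", "otu2", "otu3", "otu4")))
  storage.mode(m) <- "integer"
  m
}

toy_taxonomy <- function() {
  taxonomy_table(
    c("otu1", "otu2", "otu3", "otu4"),
    c("d__Bacteria;p__Firmicutes;c__Clostridia;o__;f__Lachnospiraceae",
      "d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__;f__Prevotellaceae",
      "d__Bacteria;p__Firmicutes;c__Bacilli",
      "d__Bacteria;p__Verrucomicrobiota"))
}

toy_metadata <- function(n_control = 4, n_survey = 3, n_acute = 3, seed = 1) {
  set.seed(seed)
  n <- n_control + n_survey + n_acute
  validate_meta <- get("validate_metadata", envir = asNamespace("equibiome"))
  validate_meta(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    status = rep(c("control", "survey_ibd", "acute_ibd"),
                 c(n_control, n_survey, n_acute)),
    age = round(runif(n, 2, 22), 1),
    gender = sample(c("mare", "gelding_stallion"), n, replace = TRUE),
    bcs = sample(seq(2, 4, 0.5), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

random_counts <- function(n, p, seed, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("otu%03d", seq_len(p))))
  storage.mode(m) <- "integer"
  m
}

small_cohort <- function(preset = "paper", seed = 1, n_otus = 400, n_da = 20, ...) {
  generate_cohort(synthetic_config(preset, n_otus = n_otus, n_da = n_da, ...),
                  seed = seed)
}
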