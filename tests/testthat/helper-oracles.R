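# Independent oracles and random-case generators used by the property
# tests. These deliberately avoid the package's own computation paths.

# loop-based minimum (oracle for the min t-norm)
brute_min <- function(x) {
  m <- Inf
  for (v in x) if (v < m) m <- v
  m
}

# explicit double-loop observed/expected agreement (oracle for kappa)
brute_agreement <- function(counts) {
  n <- sum(counts)
  pa <- 0
  pe <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (i == j) pa <- pa + counts[i, j] / n
    }
    ri <- sum(counts[i, ]) / n
    ci <- sum(counts[, i]) / n
    pe <- pe + ri * ci
  }
  list(p_a = pa, p_e = pe)
}

# random square confusion matrix with non-degenerate marginals
rand_confusion <- function(k) {
  repeat {
    m <- matrix(sample(0:25, k * k, replace = TRUE), k, k,
                dimnames = list(paste0("c", 1:k), paste0("c", 1:k)))
    if (sum(m) > 0) {
      p <- m / sum(m)
      if (1 - sum(rowSums(p) * colSums(p)) > 1e-6) return(confusion_matrix(m))
    }
  }
}

# random conjunctive rule plus matching fuzzified/crisp inputs
rand_rule_case <- function() {
  n_fuzzy <- sample(1:3, 1)
  n_crisp <- sample(0:2, 1)
  fuzzified <- list()
  ante <- character()
  for (i in seq_len(n_fuzzy)) {
    terms <- paste0("t", seq_len(sample(2:4, 1)))
    degs <- stats::setNames(round(stats::runif(length(terms)), 3), terms)
    vn <- paste0("f", i)
    fuzzified[[vn]] <- degs
    ante[vn] <- sample(terms, 1)
  }
  crisp <- character()
  for (i in seq_len(n_crisp)) {
    vn <- paste0("c", i)
    crisp[vn] <- sample(c("yes", "no"), 1)
    ante[vn] <- sample(c("yes", "no"), 1)
  }
  expected <- brute_min(c(
    vapply(names(fuzzified), function(v) fuzzified[[v]][[ante[v]]], numeric(1)),
    if (length(crisp)) as.numeric(crisp == ante[names(crisp)]) else numeric(0)))
  list(rule = fuzzy_rule(ante, "out", "term"), fuzzified = fuzzified,
       crisp = crisp, expected = expected)
}

# a case satisfying every crisp migraine criterion
rand_definite_mo_case <- function() {
  patient_case(
    number_of_attacks = sample(5:40, 1),
    duration_low = stats::runif(1, 4, 30),
    duration_high = stats::runif(1, 30, 72),
    intensity_vas = stats::runif(1, 4, 10),
    location = "unilateral", quality = "pulsating",
    aggravation_by_activity = "yes", nausea = "yes",
    vomiting = sample(c("yes", "no"), 1), photophobia = "no",
    phonophobia = "no")
}

rand_case <- function() {
  dl <- stats::runif(1, 0.1, 100)
  patient_case(
    number_of_attacks = sample(0:30, 1),
    duration_low = dl, duration_high = dl * stats::runif(1, 1, 3),
    intensity_vas = stats::runif(1, 0, 10),
    location = sample(c("unilateral", "bilateral"), 1),
    quality = sample(c("pulsating", "non-pulsating", "other"), 1),
    aggravation_by_activity = sample(c("yes", "no"), 1),
    nausea = sample(c("yes", "no"), 1),
    vomiting = sample(c("yes", "no"), 1),
    photophobia = sample(c("yes", "no"), 1),
    phonophobia = sample(c("yes", "no"), 1))
}
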