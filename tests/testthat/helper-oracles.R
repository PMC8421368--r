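# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (explicit loops, textbook formulas,
# stats-package routines) and share no code with the implementation.

# Weighted KS enrichment score by explicit walk down the ranking.
oracle_es <- function(metric, hit_positions, weight) {
  N <- length(metric)
  Nh <- length(hit_positions)
  sw <- sum(abs(metric[hit_positions])^weight)
  flat <- sw == 0
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (i %in% hit_positions)
      run <- run + if (flat) 1 / Nh else abs(metric[i])^weight / sw
    else
      run <- run - 1 / (N - Nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exact nominal p over all C(N, k) placements, observed direction.
oracle_exact_p <- function(metric, hit_positions, weight) {
  N <- length(metric)
  k <- length(hit_positions)
  es <- oracle_es(metric, hit_positions, weight)
  all_es <- apply(utils::combn(N, k), 2L,
                  function(h) oracle_es(metric, h, weight))
  p <- if (es >= 0) mean(all_es >= es - 1e-12)
       else mean(all_es <= es + 1e-12)
  list(es = es, p = p, all_es = all_es)
}

# ssGSEA partial-ECDF sum by explicit loop.
oracle_ssgsea <- function(profile, set_members, alpha) {
  nm <- names(profile)[order(-profile, names(profile))]
  N <- length(nm)
  inset <- nm %in% set_members
  rks <- N:1
  num <- 0
  denom_in <- sum(rks[inset]^alpha)
  cum_in <- 0
  cum_out <- 0
  total <- 0
  for (i in seq_len(N)) {
    if (inset[i]) cum_in <- cum_in + rks[i]^alpha
    else cum_out <- cum_out + 1
    total <- total + cum_in / denom_in - cum_out / (N - sum(inset))
  }
  total
}

# Product-limit estimator by hand.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_, n_risk = NA_real_,
                    n_event = NA_real_)
  for (i in seq_along(ut)) {
    n <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n)
    out$surv[i] <- s
    out$n_risk[i] <- n
    out$n_event[i] <- d
  }
  out
}

# Two-group log-rank statistic by hand (O, E, V over event times).
oracle_logrank2 <- function(time1, event1, time2, event2) {
  ut <- sort(unique(c(time1[event1 == 1], time2[event2 == 1])))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n1 <- sum(time1 >= t); n2 <- sum(time2 >= t); n <- n1 + n2
    d1 <- sum(time1 == t & event1 == 1)
    d2 <- sum(time2 == t & event2 == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Consensus rule oracles, written as direct transcriptions of the rules.
oracle_rule_3dgmh <- function(over, sig) {
  all(over) && sum(sig & over) >= 2
}
oracle_rule_gsc <- function(over, support_any) {
  sum(over) >= 2 || (sum(over) >= 1 && support_any)
}

# Small helper: wrap a named numeric vector as a one-column tagged
# expression matrix.
as_logexpr <- function(v, sample = "s1") {
  new("LogExpressionMatrix",
      assay = matrix(v, ncol = 1, dimnames = list(names(v), sample)),
      spaceTag = "log2cpm")
}

# Flag-table constructor for the consensus engines.
flag_table <- function(genes, over, sig = rep(FALSE, length(genes))) {
  data.frame(gene = genes, overexpressed = over, significant = sig,
             stringsAsFactors = FALSE)
}
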