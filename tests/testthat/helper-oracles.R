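# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the exact binomial interval is inverted with a
# root-finder on pbinom, the AUC counts pairs exhaustively, and the any-of
# evaluator is a scalar re-implementation of the rule semantics.

cp_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  c(lo, hi)
}

auc_oracle <- function(scores, truth) {
  truth <- as.logical(truth)
  s1 <- scores[truth]; s0 <- scores[!truth]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Scalar any-of verdict from named item values (TRUE/FALSE/NA).
brute_any_of <- function(vals, policy = "complete_case") {
  if (policy == "complete_case" && anyNA(vals)) return("not_evaluable")
  v <- vals
  v[is.na(v)] <- FALSE
  if (any(v)) "positive" else "negative"
}

# A small fully-recorded dataset with controlled outcomes for pipeline tests.
make_tiny_dataset <- function(n = 12, cases = 4, name = "tiny", seed = 7) {
  withr::with_seed(seed, {
    rec <- tibble::tibble(
      record_id = sprintf("t%03d", seq_len(n)),
      age_months = round(runif(n, 2, 60), 1),
      clinician_instinct = rbinom(n, 1, 0.3),
      dyspnea = rbinom(n, 1, 0.2),
      temperature = round(runif(n, 36.5, 40.5), 1),
      diarrhea = rbinom(n, 1, 0.2),
      petechiae = 0L, nuchal_rigidity = 0L, coma = 0L,
      sepsis = 0L, meningitis = 0L, pneumonia = 0L,
      osteomyelitis = 0L, cellulitis = 0L, complicated_uti = 0L
    )
    rec$sepsis[seq_len(cases)] <- 1L
    patient_dataset(rec, name = name, setting = "GP", country = "XX")
  })
}

# One record as a named list, defaulting every FSDT-relevant field to "no".
fsdt_record <- function(...) {
  rec <- list(age_months = 48, clinician_instinct = 0, dyspnea = 0,
              temperature = 37.0, diarrhea = 0)
  utils::modifyList(rec, list(...))
}
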