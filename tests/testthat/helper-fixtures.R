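# fixture builders used across the suite

make_admissions <- function(n, los = 5L, surgical = FALSE, icu = FALSE,
                            obstetric = FALSE, coded_hac = FALSE) {
  tibble::tibble(admission_id = seq_len(n), adult = TRUE,
                 obstetric = rep_len(obstetric, n),
                 surgical = rep_len(surgical, n),
                 icu = rep_len(icu, n),
                 length_of_stay = rep_len(as.integer(los), n),
                 coded_hac = rep_len(coded_hac, n))
}

# every admission holds exactly `k` hypoglycemia events on distinct days
make_uniform_cohort <- function(n, k = 2L, severe = FALSE, los = NULL) {
  if (is.null(los)) los <- max(k, 1L)
  adm <- make_admissions(n, los = los)
  ev <- tibble::tibble(
    admission_id = rep(seq_len(n), each = k),
    day = rep(seq_len(k) - 1L, times = n),
    category = if (isTRUE(severe)) "severe_hypo" else "nonsevere_hypo")
  cohort(adm, ev)
}

# mixed-severity cohort: per admission, `s` severe and `ns` non-severe
make_mixed_cohort <- function(s, ns, los = NULL) {
  stopifnot(length(s) == length(ns))
  n <- length(s)
  k <- s + ns
  if (is.null(los)) los <- max(k, 1L)
  adm <- make_admissions(n, los = los)
  ev <- tibble::tibble(
    admission_id = rep(seq_len(n), times = k),
    day = unlist(lapply(k, function(x) seq_len(x) - 1L), use.names = FALSE),
    category = unlist(mapply(function(a, b) c(rep("severe_hypo", a),
                                              rep("nonsevere_hypo", b)),
                             s, ns, SIMPLIFY = FALSE), use.names = FALSE))
  cohort(adm, ev)
}
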