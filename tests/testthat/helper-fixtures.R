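# Shared fixtures and independent oracles, all built in code.

# write a tiny three-table cohort to a temp dir; returns the paths
write_toy_cohort <- function(dir = NULL,
                             mutations = NULL, cytogenetics = NULL,
                             clinical = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cohort")
    dir.create(dir)
  }
  if (is.null(mutations)) {
    mutations <- data.frame(
      patient_id = c("P1", "P1", "P2", "P3"),
      gene = c("NPM1", "DNMT3A", "FLT3", "TP53"),
      vaf = c(0.42, 0.38, NA, 0.71),
      consequence = c("indel", "substitution", "itd", "substitution"),
      oncogenic = TRUE)
  }
  if (is.null(cytogenetics)) {
    cytogenetics <- data.frame(
      patient_id = c("P1", "P2", "P3"),
      lesions = c("+8", "", "del(5q),-7,del(17p)"),
      karyotype_available = TRUE)
  }
  if (is.null(clinical)) {
    clinical <- data.frame(
      patient_id = c("P1", "P2", "P3"),
      age_years = c(54, 61, 70), sex = c("F", "M", "M"),
      wbc = c(25, 8, 3), hb = c(9.1, 10.2, 8.5),
      platelets = c(60, 110, 45), bm_blast_pct = c(70, 40, 30),
      ahd = c(FALSE, FALSE, TRUE),
      performance_status = c(0, 1, 1),
      disease_type = c("de_novo", "de_novo", "sAML"),
      flt3_itd_ratio = c(NA, 0.6, NA),
      t_cr = c(0.2, NA, NA), t_relapse = c(1.1, NA, NA),
      t_last = c(2.0, 1.5, 0.4), dead = c(TRUE, FALSE, TRUE))
  }
  paths <- file.path(dir, c("mutations.tsv", "cytogenetics.tsv",
                            "clinical.tsv"))
  write.table(mutations, paths[1], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(cytogenetics, paths[2], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(clinical, paths[3], sep = "\t", row.names = FALSE,
              quote = FALSE)
  list(dir = dir, mutations = paths[1], cytogenetics = paths[2],
       clinical = paths[3])
}

# quick single-patient profile builders
profile_with <- function(genes = character(), cyto = character(),
                         consequence = "substitution", itd = FALSE,
                         itd_ratio = NA_real_, vaf = NA_real_,
                         id = "pt") {
  muts <- if (length(genes))
    mutation_calls(genes, vaf = vaf, consequence = consequence)
  else empty_mutations()
  if (itd) muts <- rbind(muts, mutation_calls("FLT3",
                                              consequence = "itd"))
  lesion_profile(id, mutations = muts, cytogenetics = cyto,
                 flt3_itd_ratio = itd_ratio)
}

# adjusted Rand index (independent implementation for recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  expected <- si * sj / sn
  (sij - expected) / ((si + sj) / 2 - expected)
}

# planted-partition binary matrix: K blocks with private high-probability
# features over a weak background
planted_matrix <- function(n, K, d_per = 3, p_sig = 0.9, p_bg = 0.02,
                           seed = 1) {
  set.seed(seed)
  lab <- rep_len(seq_len(K), n)
  d <- K * d_per
  x <- matrix(rbinom(n * d, 1, p_bg), n, d)
  for (k in seq_len(K)) {
    cols <- (k - 1) * d_per + seq_len(d_per)
    x[lab == k, cols] <- rbinom(sum(lab == k) * d_per, 1, p_sig)
  }
  colnames(x) <- paste0("feat", seq_len(d))
  list(x = x, labels = lab)
}

# brute-force Harrell concordance (O(n^2) pair enumeration oracle)
harrell_oracle <- function(risk, time, status = rep(1, length(time))) {
  n <- length(risk)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    if (status[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  num / den
}

# empirical state occupancy by direct counting (zero-censoring oracle):
# state of each patient at time t from the raw outcome timepoints
counting_occupancy <- function(outcomes, t) {
  states <- state_space()$states
  counts <- setNames(numeric(6), states)
  for (i in seq_len(nrow(outcomes))) {
    t_cr <- outcomes$t_cr[i]
    t_rel <- outcomes$t_relapse[i]
    t_last <- outcomes$t_last[i]
    dead <- outcomes$dead[i]
    st <-
      if (t < t_last) {
        if (!is.na(t_rel) && t >= t_rel) "relapse"
        else if (!is.na(t_cr) && t >= t_cr) "alive_cr"
        else "alive_induction"
      } else if (!dead) {
        # censored before t: excluded by the zero-censoring premise
        NA_character_
      } else if (is.na(t_cr)) "death_no_cr"
      else if (is.na(t_rel)) "death_in_cr"
      else "death_after_relapse"
    if (!is.na(st)) counts[st] <- counts[st] + 1
  }
  counts / sum(counts)
}
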