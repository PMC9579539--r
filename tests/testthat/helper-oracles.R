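# Independent oracles and small fixture builders shared across tests.

# Brute-force best-reference local alignment via Biostrings (independent
# of the package's own Smith-Waterman); same scoring convention.
bios_best <- function(query, refs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  scores <- vapply(refs, function(r) {
    Biostrings::pairwiseAlignment(query, r, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 2, gapExtension = 1,
                                  scoreOnly = TRUE)
  }, numeric(1))
  list(gene = names(refs)[which.max(scores)], score = max(scores))
}

# Fixed-step RK4 integration of dR/dt = ka*C*(Rmax - R) - kd*R, evaluated
# at the requested times (association, R(0) = 0) or of dR/dt = -kd*R from
# R0 (dissociation).
ode_sensorgram <- function(ka, kd, rmax, conc, times, h = 1e-3,
                           r0 = 0, dissoc = FALSE) {
  f <- if (dissoc) function(r) -kd * r
       else function(r) ka * conc * (rmax - r) - kd * r
  out <- numeric(length(times))
  t_cur <- 0
  r <- r0
  for (i in seq_along(times)) {
    while (t_cur < times[i] - 1e-12) {
      step <- min(h, times[i] - t_cur)
      k1 <- f(r)
      k2 <- f(r + step / 2 * k1)
      k3 <- f(r + step / 2 * k2)
      k4 <- f(r + step * k3)
      r <- r + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + step
    }
    out[i] <- r
  }
  out
}

# Scaled-down three-mouse repertoire fixture for fast tests.
small_repertoire_config <- function(...) {
  repertoire_config(cells_per_mouse = c(200L, 180L, 20L), ...)
}

# Run the repertoire pipeline (alignment + clonotype table) on a
# simulated fixture using truth donors.
run_repertoire_stage <- function(sim) {
  light <- sim$contigs[sim$contigs$chain == "IGK", ]
  calls <- call_germlines(sim$sequences[light$contig_id], sim$reference)
  suppressMessages(build_clonotype_table(sim$contigs, calls,
                                         sequences = sim$sequences))
}
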