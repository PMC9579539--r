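#' End-to-end pipeline configuration
#'
#' Bundles the per-module configurations, stage toggles and the master
#' seed.  All randomness flows from `seed` (each stage derives its own
#' offset), so a config run twice produces byte-identical artifacts.
#'
#' @param outdir output directory (created if needed).
#' @param seed master integer seed.
#' @param stages named logical vector toggling `demux`, `repertoire`,
#'   `transcriptome`, `binding` (simulation always runs: it provides the
#'   inputs of every enabled stage).
#' @param repertoire a [repertoire_config()].
#' @param hashtag a [hashtag_config()].
#' @param expression an [expression_config()].
#' @param spr an [spr_config()].
#' @param demux_k,demux_margin demultiplexing parameters.
#' @param elisa_groups named list: per antibody group, its `od_max` and
#'   replicate count for the simulated ELISA curves.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c(demux = TRUE, repertoire = TRUE,
                                       transcriptome = TRUE,
                                       binding = TRUE),
                            repertoire = repertoire_config(),
                            hashtag = hashtag_config(),
                            expression = expression_config(),
                            spr = spr_config(),
                            demux_k = 2, demux_margin = 1,
                            elisa_groups = list(
                              "Vk4-74" = list(od_max = 2.5, n = 4),
                              "Vk4-57" = list(od_max = 1.6, n = 4),
                              "non-Vk4" = list(od_max = 0.15, n = 4))) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 stages = stages, repertoire = repertoire,
                 hashtag = hashtag, expression = expression, spr = spr,
                 demux_k = demux_k, demux_margin = demux_margin,
                 elisa_groups = elisa_groups),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate -> demux -> repertoire
#' -> transcriptome -> binding), writes every artifact under
#' `config$outdir` (contig CSV/FASTA, germline FASTA, hashtag matrix,
#' expression matrix, atlas CSV, clonotype frequency CSVs, marker CSV,
#' signature CSV, sensorgram and ELISA CSVs, fit report) plus a
#' machine-readable `summary.json`.  A stage failure aborts with the
#' stage name and cause; artifacts already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly; the same content is written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  enabled <- function(s) isTRUE(config$stages[[s]])
  summary <- list(seed = config$seed)

  # --- simulate ------------------------------------------------------
  sim <- on_stage("simulate", {
    rep_sim <- simulate_repertoire(config$repertoire, config$seed)
    truth_hash <- setNames(rep_sim$truth$donor, rep_sim$truth$barcode)
    hash <- simulate_hashtags(config$hashtag, truth_hash,
                              config$seed + 1L)
    expr <- simulate_expression(config$expression, config$seed + 2L)
    atlas <- make_reference_atlas(seed = config$seed + 3L)
    spr_raw <- simulate_sensorgram(config$spr, config$seed + 4L)
    elisa <- do.call(rbind, lapply(seq_along(config$elisa_groups),
      function(i) {
        g <- names(config$elisa_groups)[i]
        spec <- config$elisa_groups[[i]]
        do.call(rbind, lapply(seq_len(spec$n), function(r) {
          cv <- simulate_elisa(od_max = spec$od_max,
                               seed = config$seed + 10L * i + r,
                               group = g)
          cv$replicate <- r
          cv
        }))
      }))
    write_contig_annotations(rep_sim$contigs, out("contigs.csv"))
    write_contig_fasta(rep_sim$sequences, out("contigs.fasta"))
    write_germline_fasta(rep_sim$reference, out("germline.fasta"))
    write.csv(rep_sim$truth, out("truth_clonotypes.csv"),
              row.names = FALSE, na = "")
    write_matrix(hash$counts, out("hashtags.mtx"))
    write_matrix(expr$counts, out("expression.mtx"))
    write_atlas_csv(atlas, out("atlas.csv"))
    write_sensorgram_csv(spr_raw, out("sensorgrams.csv"))
    write_elisa_csv(elisa, out("elisa.csv"))
    list(rep = rep_sim, hash = hash, expr = expr, atlas = atlas,
         spr = spr_raw, elisa = elisa)
  })
  summary$n_cells <- nrow(sim$rep$truth)

  assignments <- NULL
  if (enabled("demux")) {
    assignments <- on_stage("demux", {
      a <- demultiplex(sim$hash$counts, k = config$demux_k,
                       margin = config$demux_margin)
      write.csv(as.data.frame(a), out("assignments.csv"),
                row.names = FALSE)
      a
    })
    counts <- table(factor(assignments$state,
                           levels = c(as.character(
                             seq_len(config$hashtag$n_hashtags)),
                             "unassigned", "multiplet")))
    summary$demux <- list(
      per_donor = as.list(setNames(as.integer(counts), names(counts))))
  }

  if (enabled("repertoire")) {
    summary$repertoire <- on_stage("repertoire", {
      light <- sim$rep$contigs[sim$rep$contigs$chain == "IGK", ]
      seqs <- sim$rep$sequences[light$contig_id]
      calls <- call_germlines(seqs, sim$rep$reference)
      ctab <- suppressMessages(build_clonotype_table(
        sim$rep$contigs, calls, assignments = assignments,
        sequences = sim$rep$sequences))
      write.csv(data.frame(rearrangement = rownames(ctab$pair_freq),
                           ctab$pair_freq, check.names = FALSE),
                out("rearrangement_frequencies.csv"), row.names = FALSE)
      write.csv(data.frame(v_gene = rownames(ctab$v_freq), ctab$v_freq,
                           check.names = FALSE),
                out("v_gene_frequencies.csv"), row.names = FALSE)
      write.csv(ctab$cells, out("clonotype_cells.csv"),
                row.names = FALSE, na = "")
      top <- rownames(ctab$pair_freq)[1]
      list(kappa_fraction = ctab$kappa_fraction,
           n_excluded = ctab$n_excluded,
           top_rearrangement = top,
           top_frequency = unname(ctab$pair_freq[1, "mean"]))
    })
  }

  if (enabled("transcriptome")) {
    summary$transcriptome <- on_stage("transcriptome", {
      norm <- normalize_counts(sim$expr$counts)
      clus <- cluster_cells(norm, seed = config$seed + 5L)
      markers <- find_markers(norm, clus$labels)
      write.csv(markers$significant, out("markers.csv"),
                row.names = FALSE)
      write.csv(data.frame(barcode = rownames(norm),
                           cluster = clus$labels),
                out("clusters.csv"), row.names = FALSE)
      up <- split(markers$significant$gene[
        markers$significant$direction == "up"],
        markers$significant$cluster[
          markers$significant$direction == "up"])
      mapped <- map_genes(unique(markers$significant$gene), sim$atlas)
      proj <- project_to_atlas(mapped$mapped, sim$atlas,
                               cluster_markers = lapply(up, intersect,
                                                        y = mapped$mapped))
      write.csv(data.frame(gene = rownames(proj$z), proj$z,
                           check.names = FALSE),
                out("signature_matrix.csv"), row.names = FALSE)
      list(n_clusters = clus$k,
           cluster_sizes = as.integer(clus$sizes),
           n_markers = length(unique(markers$significant$gene)),
           n_unmapped = length(mapped$unmapped),
           population_assignment = as.list(proj$assignment))
    })
  }

  if (enabled("binding")) {
    summary$binding <- on_stage("binding", {
      prep <- preprocess_sensorgram(sim$spr)
      fit <- fit_langmuir(prep)
      aucs <- do.call(rbind, lapply(
        split(sim$elisa, list(sim$elisa$group, sim$elisa$replicate),
              drop = TRUE),
        function(d) data.frame(group = d$group[1],
                               replicate = d$replicate[1],
                               auc = elisa_auc(d))))
      write.csv(aucs, out("elisa_auc.csv"), row.names = FALSE)
      cmp <- compare_groups(aucs$auc, aucs$group)
      fit_report <- list(ka = fit$ka, kd = fit$kd, kD = fit$kD,
                         rmax = fit$rmax, rms = fit$rms,
                         se = as.list(fit$se),
                         converged = fit$converged)
      jsonlite::write_json(fit_report, out("kinetic_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      list(kinetics = fit_report,
           elisa_anova_p = cmp$p,
           auc_means = as.list(tapply(aucs$auc, aucs$group, mean)))
    })
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
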