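#' Run the candidate-imprinted-gene screen
#'
#' Calls peaks from coverage when coverage is supplied (otherwise consumes
#' pre-called peak sets directly), profiles every promoter, applies the
#' selection criterion (all three marks plus a CpG island), and runs the
#' haploid-chromosome internal control. Outputs are deterministic and, if
#' \code{out_dir} is given, written as candidates.tsv, screen_summary.json
#' and venn.json plus per-mark peak BED files.
#'
#' @param ann [annotation()] object.
#' @param coverage optional list with \code{treatment} (named list of
#'   [coverage_track()]s for H3K4me3, H3K9Ac, H3K9me3) and \code{input}.
#' @param peaksets optional named list of pre-called peak interval tables
#'   (used when \code{coverage} is NULL).
#' @param promoter_cfg [promoter_config()].
#' @param peak_cfg [peak_caller_config()].
#' @param force_include gene ids carried into the candidate list
#'   regardless of profile (known-imprinted genes lacking the signature).
#' @param out_dir optional output directory.
#' @return list of class \code{screen_result}: \code{profiles},
#'   \code{candidates}, \code{summary}, \code{venn}, \code{violations},
#'   \code{peaksets}.
#' @export
run_screen <- function(ann, coverage = NULL, peaksets = NULL,
                       promoter_cfg = promoter_config(),
                       peak_cfg = peak_caller_config(),
                       force_include = character(), out_dir = NULL) {
  marks <- c("H3K4me3", "H3K9Ac", "H3K9me3")
  if (!is.null(coverage)) {
    miss <- setdiff(marks, names(coverage$treatment))
    if (length(miss)) fail("missing coverage for mark '%s'", miss[1])
    peaksets <- lapply(coverage$treatment[marks], call_peaks,
                       control = coverage$input, cfg = peak_cfg)
  }
  if (is.null(peaksets)) fail("supply either coverage or peaksets")
  miss <- setdiff(marks, names(peaksets))
  if (length(miss)) fail("missing peak set for mark '%s'", miss[1])
  profiles <- profile_promoters(ann, peaksets, promoter_cfg)
  candidates <- select_candidates(profiles, force_include)
  summary <- screen_summary(profiles)
  venn <- venn_counts(peaksets[marks])
  violations <- haploid_control_check(candidates, ann)
  res <- structure(list(profiles = profiles, candidates = candidates,
                        summary = summary, venn = venn,
                        violations = violations, peaksets = peaksets),
                   class = "screen_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cand_tab <- profiles[profiles$gene_id %in% candidates, ]
    utils::write.table(cand_tab, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_screen_summary(summary,
                         file.path(out_dir, "screen_summary.json"))
    write_venn_json(venn, file.path(out_dir, "venn.json"))
    for (m in marks) {
      write_peaks(peaksets[[m]],
                  file.path(out_dir, paste0(m, "_peaks.bed")), label = m)
    }
  }
  res
}

#' Classify candidate genes from reciprocal-cross data
#'
#' For every candidate gene: genotypes all pedigree members from gDNA
#' allele pileups, determines which F1 animals carry a trackable SNP
#' (heterozygous, with unambiguous parental assignment), converts
#' replicate-averaged pyrosequencing percentages into maternal-allele
#' fractions, and calls the gene imprinted (with direction), allele
#' biased, biallelic, or undetermined. Mendelian inconsistencies abort
#' that gene's classification with an \code{error} row; the run continues.
#' Genes with no trackable SNP in any animal are \code{undetermined} with
#' reason "no trackable SNP".
#'
#' @param candidates character vector of gene ids.
#' @param gdna data.frame of gDNA pileups: \code{gene_id}, \code{sample},
#'   \code{count1}, \code{count2}.
#' @param pedigree data.frame: \code{family_id}, \code{cross_type}
#'   (\code{AxB} = stock-A dam; \code{BxA} = stock-B dam), \code{mother},
#'   \code{father}, \code{animal}.
#' @param pyro data.frame of replicate percentages of allele 1:
#'   \code{gene_id}, \code{animal}, \code{replicate},
#'   \code{percent_allele1}.
#' @param snp_cfg [snp_config()].
#' @param bias_threshold percent bias threshold for [classify_gene()].
#' @param replicate_tolerance replicate-discordance tolerance (points).
#' @param out_dir optional output directory (imprint_calls.tsv).
#' @return data.frame with one row per candidate: \code{gene_id},
#'   \code{call}, \code{leakage}, \code{n_informative}, \code{reason}.
#' @export
run_classify <- function(candidates, gdna, pedigree, pyro,
                         snp_cfg = snp_config(), bias_threshold = 70,
                         replicate_tolerance = 3, out_dir = NULL) {
  rows <- lapply(candidates, function(gid) {
    gd <- gdna[gdna$gene_id == gid, , drop = FALSE]
    if (nrow(gd) == 0L) {
      return(data.frame(gene_id = gid, call = "undetermined",
                        leakage = NA_real_, n_informative = 0L,
                        reason = "no SNP pileup data",
                        stringsAsFactors = FALSE))
    }
    geno <- stats::setNames(call_het_snps(gd$count1, gd$count2, snp_cfg),
                            gd$sample)
    meas <- list()
    inconsistent <- FALSE
    for (r in seq_len(nrow(pedigree))) {
      animal <- pedigree$animal[r]
      if (!animal %in% names(geno)) next
      lookup <- function(s) {
        v <- unname(geno[s])
        if (length(v) != 1L || is.na(v)) "no_call" else v
      }
      tr <- trackable(lookup(animal), lookup(pedigree$mother[r]),
                      lookup(pedigree$father[r]))
      if (tr$status == "inconsistent") {
        inconsistent <- TRUE
        break
      }
      if (tr$status != "informative") next
      py <- pyro[pyro$gene_id == gid & pyro$animal == animal, ,
                 drop = FALSE]
      if (nrow(py) == 0L) next
      af <- allele_fraction(py$percent_allele1, replicate_tolerance)
      maternal_fraction <- if (tr$maternal_allele == 1L) af$fraction
      else 100 - af$fraction
      meas[[length(meas) + 1L]] <- data.frame(
        animal = animal, cross_type = pedigree$cross_type[r],
        maternal_fraction = maternal_fraction,
        maternal_stock = substr(pedigree$cross_type[r], 1, 1),
        discordant = af$discordant, stringsAsFactors = FALSE)
    }
    if (inconsistent) {
      return(data.frame(gene_id = gid, call = "error",
                        leakage = NA_real_, n_informative = 0L,
                        reason = "Mendelian inconsistency in pedigree",
                        stringsAsFactors = FALSE))
    }
    if (!length(meas)) {
      return(data.frame(gene_id = gid, call = "undetermined",
                        leakage = NA_real_, n_informative = 0L,
                        reason = "no trackable SNP",
                        stringsAsFactors = FALSE))
    }
    m <- do.call(rbind, meas)
    call <- classify_gene(m, bias_threshold = bias_threshold,
                          gene_id = gid)
    data.frame(gene_id = gid, call = call$call, leakage = call$leakage,
               n_informative = nrow(m), reason = call$reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res, file.path(out_dir, "imprint_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Run the full pipeline on a synthetic truth set
#'
#' Chains the simulator and both analysis stages: builds the truth set,
#' simulates ChIP coverage, calls peaks and screens promoters, simulates
#' allele pileups and pyrosequencing, classifies every candidate, and
#' summarizes bisulfite methylation for the planted amplicons. Re-running
#' with the same config reproduces every output exactly.
#'
#' @param cfg [truth_config()].
#' @param out_dir optional output directory for all stage outputs.
#' @param promoter_cfg,peak_cfg,snp_cfg stage configurations.
#' @param bias_threshold,replicate_tolerance classification thresholds,
#'   passed to [run_classify()].
#' @return list of class \code{pipeline_result}: \code{truth},
#'   \code{screen}, \code{calls}, \code{methylation}.
#' @export
run_all <- function(cfg = truth_config(), out_dir = NULL,
                    promoter_cfg = promoter_config(),
                    peak_cfg = peak_caller_config(),
                    snp_cfg = snp_config(), bias_threshold = 70,
                    replicate_tolerance = 3) {
  truth <- build_truth(cfg)
  chip <- simulate_chip(truth)
  screen <- run_screen(truth$annotation, coverage = chip,
                       promoter_cfg = promoter_cfg, peak_cfg = peak_cfg,
                       out_dir = out_dir)
  reads <- simulate_allelic_reads(truth)
  calls <- run_classify(screen$candidates, reads$gdna, reads$pedigree,
                        reads$pyro, snp_cfg = snp_cfg,
                        bias_threshold = bias_threshold,
                        replicate_tolerance = replicate_tolerance,
                        out_dir = out_dir)
  clones <- simulate_bisulfite(truth)
  methylation <- lapply(clones, function(cl) {
    mat <- tabulate_clones(cl$amplicon, cl$clones)
    list(gene_id = cl$gene_id,
         summary = summarize_region(mat),
         dmr = allele_dmr_test(mat))
  })
  if (!is.null(out_dir)) {
    # every threshold used by any stage, echoed for provenance
    log_lines <- c(
      sprintf("seed\t%s", cfg$seed),
      sprintf("promoter_upstream\t%s", promoter_cfg$upstream),
      sprintf("promoter_downstream\t%s", promoter_cfg$downstream),
      sprintf("peak_p_threshold\t%g", peak_cfg$p_threshold),
      sprintf("peak_bin_width\t%s", peak_cfg$bin_width),
      sprintf("peak_local_scales\t%s",
              paste(peak_cfg$local_scales, collapse = ",")),
      sprintf("peak_merge_gap\t%s", peak_cfg$merge_gap),
      sprintf("peak_min_length\t%s", peak_cfg$min_length),
      sprintf("snp_min_coverage\t%s", snp_cfg$min_coverage),
      sprintf("snp_min_minor_fraction\t%s", snp_cfg$min_minor_fraction),
      sprintf("bias_threshold\t%s", bias_threshold),
      sprintf("replicate_tolerance\t%s", replicate_tolerance))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    meth_json <- lapply(methylation, function(m) {
      list(gene_id = m$gene_id, status = m$summary$status,
           mean_fraction = m$summary$mean_fraction,
           dmr_verdict = m$dmr$verdict)
    })
    jsonlite::write_json(meth_json,
                         file.path(out_dir, "methylation_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(truth = truth, screen = screen, calls = calls,
                 methylation = methylation),
            class = "pipeline_result")
}

#' Score pipeline calls against the planted truth
#'
#' Convenience for synthetic runs: joins the classification table with the
#' truth labels and reports recovery statistics.
#'
#' @param result [run_all()] output.
#' @return list with \code{candidate_recall} (fraction of planted
#'   imprinted genes among candidates), \code{direction_accuracy}
#'   (fraction of planted imprinted genes called with the correct
#'   parental direction), \code{false_imprinted} (planted biallelic genes
#'   called imprinted), \code{haploid_candidates}, and the joined
#'   \code{table}.
#' @export
score_truth_recovery <- function(result) {
  truth <- result$truth$genes
  calls <- result$calls
  imp <- truth[truth$class %in% c("imprinted_maternal",
                                  "imprinted_paternal"), ]
  cand <- result$screen$candidates
  recall <- mean(imp$gene_id %in% cand)
  joined <- merge(calls, truth[, c("gene_id", "class")], by = "gene_id")
  expected <- paste0(joined$class, "_expressed")
  expected[!joined$class %in% c("imprinted_maternal",
                                "imprinted_paternal")] <- NA
  imp_rows <- joined$class %in% c("imprinted_maternal",
                                  "imprinted_paternal")
  direction_accuracy <- if (any(imp_rows)) {
    mean(joined$call[imp_rows] == expected[imp_rows])
  } else NA_real_
  false_imprinted <- sum(joined$class == "expressed_biallelic" &
                           grepl("^imprinted", joined$call))
  list(candidate_recall = recall,
       direction_accuracy = direction_accuracy,
       false_imprinted = false_imprinted,
       haploid_candidates = length(result$screen$violations),
       table = joined)
}
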