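# Full multi-set analysis pipeline: takes one FASTA (or record list) per
# virus plus host references, computes every index, and writes the standard
# table/plot-data surface as TSV. The pipeline is deterministic: no random
# draws, fixed numeric formatting, no timestamps — re-running on identical
# inputs is byte-identical.

.fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

.write_table <- function(df, path, meta, digits = 2, full = TRUE) {
  render <- function(d, dg) {
    out <- df
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(col) {
      if (is.null(dg)) format(col, digits = 15, trim = TRUE) else
        .fmt_num(col, dg)
    })
    c(meta, paste(names(out), collapse = "\t"),
      do.call(paste, c(unname(as.list(out)), sep = "\t")))
  }
  writeLines(render(df, digits), path)
  if (full) {
    writeLines(render(df, NULL), sub("\\.tsv$", ".full.tsv", path))
  }
  path
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full codon-usage-bias analysis
#'
#' Orchestrates the whole analysis over several sets of coding sequences
#' (one per virus): composition profiles, per-virus and grand-mean RSCU
#' with host comparison, ENC and its null curve, dinucleotide odds ratios,
#' CAI/RCDI against each host, PR2 coordinates, per-virus neutrality
#' regressions, pooled correspondence analysis on RSCU, and the index
#' correlation matrix. Results are written as TSV files (2-decimal
#' table renderings plus `.full.tsv` full-precision companions), each with
#' a header comment carrying the package version, a configuration hash and
#' the decision flags.
#'
#' @param sets named list: virus label -> FASTA path or list of
#'   `cds_record`.
#' @param hosts host references: character vector of packaged fixture
#'   species (see [host_reference()]) and/or a named list of
#'   `reference_usage`.
#' @param out_dir output directory (created if needed).
#' @param cai_host which host's CAI feeds the correlation matrix.
#' @param strict strict CDS validation (error on partial codons).
#' @param pr2_fourfold restrict PR2 tallies to fourfold-degenerate
#'   families.
#' @param per_virus_correlations also write one correlation matrix per
#'   virus.
#' @return Invisibly, a list with the per-sequence index table
#'   (`per_seq`), per-virus RSCU means, the pooled `coa_result`,
#'   neutrality fits, dinucleotide summaries, correlation matrices and the
#'   paths written.
#' @export
run_codon_usage_analysis <- function(sets, hosts = c("apis_mellifera",
                                                     "apis_cerana",
                                                     "vespa_velutina",
                                                     "varroa_destructor"),
                                     out_dir,
                                     cai_host = NULL,
                                     strict = FALSE,
                                     pr2_fourfold = FALSE,
                                     per_virus_correlations = FALSE) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("'sets' must be a uniquely named list of virus inputs")
  }
  stage <- function(name, virus, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' (%s): %s", name, virus, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.character(hosts)) {
    hosts <- stats::setNames(lapply(hosts, host_reference), hosts)
  }
  stopifnot(length(hosts) >= 1, !is.null(names(hosts)))
  if (is.null(cai_host)) cai_host <- names(hosts)[1]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- lapply(names(sets), function(v) {
    stage("read", v, {
      x <- sets[[v]]
      if (is.character(x)) x <- read_cds_fasta(x, strict = strict)
      if (length(x) == 0L) stop("no sequences")
      x
    })
  })
  names(records) <- names(sets)

  per_seq <- list()
  rscu_tables <- list()
  dinuc_profiles <- list()
  log_notes <- character(0)
  for (v in names(records)) {
    for (rec in records[[v]]) {
      row <- stage("indices", v, {
        counts <- count_codons(rec)
        prof <- composition_profile(rec)
        er <- enc_observed(counts)
        if (length(er$notes)) {
          log_notes <<- c(log_notes, sprintf("%s/%s: %s", v, rec$id,
                                             paste(er$notes, collapse = "; ")))
        }
        p2 <- pr2_point(counts, fourfold_only = pr2_fourfold)
        ad <- lapply(hosts, function(h) {
          list(cai = cai(counts, h), rcdi = rcdi(counts, h))
        })
        cbind(data.frame(virus = v, stringsAsFactors = FALSE), prof,
              data.frame(enc_expected = if (is.na(prof$gc3s)) NA_real_ else
                           enc_expected(prof$gc3s),
                         pr2_x = p2$x, pr2_y = p2$y),
              stats::setNames(
                as.data.frame(lapply(ad, `[[`, "cai")),
                paste0("cai_", names(hosts))),
              stats::setNames(
                as.data.frame(lapply(ad, `[[`, "rcdi")),
                paste0("rcdi_", names(hosts))))
      })
      per_seq[[length(per_seq) + 1L]] <- row
      rscu_tables[[length(rscu_tables) + 1L]] <-
        stage("rscu", v, compute_rscu(count_codons(rec)))
      dinuc_profiles[[length(dinuc_profiles) + 1L]] <-
        stage("dinucleotides", v, dinucleotide_odds(rec))
    }
  }
  per_seq <- do.call(rbind, per_seq)
  per_seq$enc_deviation <- per_seq$enc_expected - per_seq$enc

  # pooled correspondence analysis on RSCU
  rscu_mat <- t(sapply(rscu_tables, function(t) t$rscu))
  colnames(rscu_mat) <- rscu_tables[[1]]$codon
  rownames(rscu_mat) <- per_seq$id
  coa <- stage("coa", "all", coa_rscu(rscu_mat))
  if (coa$n_imputed > 0) {
    log_notes <- c(log_notes, sprintf("coa: %d missing RSCU value(s) imputed at 1.0",
                                      coa$n_imputed))
  }
  per_seq$axis1 <- coa$row_coords[, 1]
  per_seq$axis2 <- if (ncol(coa$row_coords) >= 2) coa$row_coords[, 2] else NA_real_

  # per-virus neutrality
  neutrality <- lapply(names(records), function(v) {
    stage("neutrality", v, {
      sub <- per_seq[per_seq$virus == v, ]
      neutrality_fit(sub$gc3s, sub$gc12 / 100)
    })
  })
  names(neutrality) <- names(records)

  # per-virus and grand-mean RSCU
  rscu_by_virus <- lapply(names(records), function(v) {
    mean_rscu(rscu_tables[per_seq$virus == v])
  })
  names(rscu_by_virus) <- names(records)
  rscu_grand <- mean_rscu(rscu_by_virus)

  # dinucleotides: per-virus means and two-level grand mean
  dinuc_by_virus <- lapply(names(records), function(v) {
    mean_dinucleotide_profile(dinuc_profiles[per_seq$virus == v])
  })
  names(dinuc_by_virus) <- names(records)
  dinuc_grand <- classify_dinucleotides(
    mean_dinucleotide_profile(dinuc_by_virus))

  # correlation matrix (pooled across all sets)
  corr_data <- data.frame(
    cai = per_seq[[paste0("cai_", cai_host)]],
    gc = per_seq$gc, gc12 = per_seq$gc12,
    axis1 = per_seq$axis1, axis2 = per_seq$axis2,
    u3s = per_seq$u3s, c3s = per_seq$c3s, a3s = per_seq$a3s,
    g3s = per_seq$g3s, gc3s = per_seq$gc3s, enc = per_seq$enc,
    gravy = per_seq$gravy, aroma = per_seq$aroma)
  corr_rows <- c("u3s", "c3s", "a3s", "g3s", "gc3s", "gc12", "enc",
                 "gravy", "aroma")
  corr_cols <- c("cai", "gc", "gc12", "axis1", "axis2")
  correlations <- stage("correlations", "all",
                        correlation_matrix(corr_data, rows = corr_rows,
                                           cols = corr_cols))
  corr_per_virus <- NULL
  if (per_virus_correlations) {
    corr_per_virus <- lapply(names(records), function(v) {
      correlation_matrix(corr_data[per_seq$virus == v, ],
                         rows = corr_rows, cols = corr_cols)
    })
    names(corr_per_virus) <- names(records)
  }

  # ---- write outputs ----------------------------------------------------
  config <- list(sets = names(sets), hosts = names(hosts),
                 cai_host = cai_host, strict = strict,
                 pr2_fourfold = pr2_fourfold)
  meta <- sprintf(
    "# cubkit %s | config %s | strict=%s pr2_fourfold=%s cai_host=%s pseudocount=0.5 coa_impute=1",
    as.character(utils::packageVersion("cubkit")), .config_hash(config),
    strict, pr2_fourfold, cai_host)
  paths <- character(0)
  wt <- function(df, file, digits = 2) {
    p <- .write_table(df, file.path(out_dir, file), meta, digits)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  comp_cols <- c("a_pct", "u_pct", "g_pct", "c_pct", "gc", "u3s", "c3s",
                 "a3s", "g3s", "gc3s", "enc", "au", "au3", "gc1", "gc2",
                 "gc12", "gravy", "aroma")
  by_virus <- lapply(names(records), function(v) {
    colMeans(per_seq[per_seq$virus == v, comp_cols, drop = FALSE],
             na.rm = TRUE)
  })
  tab1 <- data.frame(item = toupper(comp_cols),
                     stats::setNames(as.data.frame(by_virus), names(records)),
                     MEAN = rowMeans(as.data.frame(by_virus)),
                     stringsAsFactors = FALSE)
  wt(tab1, "table1_composition.tsv", digits = 3)

  host_tab <- host_rscu_table()
  tab2 <- data.frame(aa = rscu_grand$aa, codon = rscu_grand$codon,
                     stats::setNames(
                       as.data.frame(lapply(rscu_by_virus, `[[`, "rscu")),
                       names(records)),
                     mean = rscu_grand$rscu,
                     host_tab[match(rscu_grand$codon, host_tab$codon),
                              c("apis_mellifera", "apis_cerana",
                                "vespa_velutina", "varroa_destructor")],
                     stringsAsFactors = FALSE)
  wt(tab2, "table2_rscu.tsv")

  tab3 <- do.call(rbind, lapply(names(records), function(v) {
    do.call(rbind, lapply(names(hosts), function(h) {
      data.frame(virus = v, host = h,
                 cai = mean(per_seq[per_seq$virus == v,
                                    paste0("cai_", h)]),
                 rcdi = mean(per_seq[per_seq$virus == v,
                                     paste0("rcdi_", h)]),
                 stringsAsFactors = FALSE)
    }))
  }))
  wt(tab3, "table3_adaptation.tsv")

  # non-significant entries rendered blank, significant ones starred
  star <- matrix(ifelse(is.na(correlations$r), "",
                        ifelse(!is.na(correlations$significant) &
                                 correlations$significant,
                               paste0(.fmt_num(correlations$r, 4), "*"), "")),
                 nrow(correlations$r), dimnames = dimnames(correlations$r))
  tab4 <- cbind(data.frame(index = rownames(star), stringsAsFactors = FALSE),
                as.data.frame(star, stringsAsFactors = FALSE))
  wt(tab4, "table4_correlations.tsv", digits = 4)

  wt(per_seq[, c("id", "virus", "gc3s", "enc", "enc_expected",
                 "enc_deviation")], "enc_plot.tsv", digits = 4)
  null_s <- seq(0, 1, by = 0.01)
  wt(data.frame(gc3s = null_s, enc_expected = enc_expected(null_s)),
     "enc_null_curve.tsv", digits = 4)
  wt(per_seq[, c("id", "virus", "pr2_x", "pr2_y")], "pr2_plot.tsv",
     digits = 4)

  neut <- do.call(rbind, lapply(names(neutrality), function(v) {
    f <- neutrality[[v]]
    data.frame(virus = v, n = f$n, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               p_value = f$p_value, mutation_pct = f$mutation_pct,
               selection_pct = f$selection_pct, stringsAsFactors = FALSE)
  }))
  wt(neut, "neutrality.tsv", digits = 4)

  n_ax <- length(coa$inertia_pct)
  wt(data.frame(axis = seq_len(n_ax), inertia_pct = coa$inertia_pct,
                singular_value = coa$singular_values),
     "coa_axes.tsv", digits = 4)
  wt(data.frame(id = rownames(coa$row_coords), virus = per_seq$virus,
                coa$row_coords), "coa_coords.tsv", digits = 4)

  dn <- data.frame(dinucleotide = dinuc_grand$dinucleotide,
                   stats::setNames(
                     as.data.frame(lapply(dinuc_by_virus, `[[`, "rho")),
                     names(records)),
                   mean = dinuc_grand$rho,
                   representation = dinuc_grand$representation,
                   stringsAsFactors = FALSE)
  wt(dn, "dinucleotides.tsv")

  log_lines <- c(meta,
                 sprintf("sets: %s", paste(sprintf("%s (n=%d)", names(records),
                                                   lengths(records)),
                                           collapse = ", ")),
                 sprintf("hosts: %s", paste(names(hosts), collapse = ", ")),
                 "decisions: trailing partial codons dropped unless strict; ambiguous codons skipped; stop codons excluded from sense statistics; RSCU of absent families treated as missing; reference pseudocount 0.5; COA missing values imputed at 1.0",
                 if (length(log_notes)) c("notes:", paste0("  ", log_notes))
                 else "notes: none")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(per_seq = per_seq, rscu_by_virus = rscu_by_virus,
                 rscu_grand = rscu_grand, coa = coa,
                 neutrality = neutrality, dinuc_by_virus = dinuc_by_virus,
                 dinuc_grand = dinuc_grand, correlations = correlations,
                 corr_per_virus = corr_per_virus,
                 out_dir = out_dir, paths = unlist(paths)))
}
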