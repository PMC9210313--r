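# End-to-end orchestration: simulate (or load) a family, then run DE,
# inheritance, regulatory-divergence, dosage and heterosis stages into one
# run directory with a manifest sufficient to reproduce the run.

#' Run the full analysis pipeline
#'
#' Executes simulate -> differential expression -> inheritance -> regulatory
#' divergence -> dosage -> heterosis prediction as one reproducible run. All
#' stage outputs are tab-delimited tables under stage subdirectories of
#' `outdir`; a `manifest.json` records the package version, every threshold,
#' the seeds, and an MD5 checksum of every written table. A failing stage
#' aborts with an error naming the stage; files of the failed stage keep a
#' `.partial` suffix.
#'
#' @param sim a [sim_config()] used to generate the inputs, or `NULL` to
#'   read them from `counts_path`/`alleles_path`/`traits_path`.
#' @param outdir run directory (created if needed).
#' @param config analysis thresholds from [load_config()].
#' @param counts_path,alleles_path,traits_path optional user-supplied input
#'   tables (see [read_count_matrix()] and friends).
#' @param skip_ase skip the regulatory-divergence and dosage stages (e.g.
#'   when no allele table is available).
#' @param cv_reps_override optionally lower the nested-CV replications for
#'   quick runs; defaults to `config$cv_reps`.
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_all <- function(sim = sim_config(), outdir, config = load_config(),
                    counts_path = NULL, alleles_path = NULL,
                    traits_path = NULL, skip_ase = FALSE,
                    cv_reps_override = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  emit <- function(df, rel) {
    path <- file.path(outdir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    .write_tsv(as.data.frame(df), paste0(path, ".partial"))
    written <<- c(written, path)
    path
  }
  seal <- function() {          # promote this stage's .partial files
    for (p in written) if (file.exists(paste0(p, ".partial")))
      file.rename(paste0(p, ".partial"), p)
  }

  ## --- inputs ---------------------------------------------------------------
  fam <- stage("io_tables", {
    if (!is.null(sim)) {
      fam <- simulate_family(sim)
      dir.create(file.path(outdir, "inputs"), showWarnings = FALSE)
      write_count_matrix(fam$counts, file.path(outdir, "inputs", "counts.tsv"))
      write_allele_table(fam$alleles, file.path(outdir, "inputs", "alleles.tsv"))
      write_trait_table(fam$traits, file.path(outdir, "inputs", "traits.tsv"))
      emit(fam$truth$genes, "inputs/truth_genes.tsv")
      emit(fam$truth$dosage, "inputs/truth_dosage.tsv")
      seal()
      fam
    } else {
      if (is.null(counts_path)) .stopf("either a sim config or counts_path is required")
      list(counts = read_count_matrix(counts_path),
           alleles = if (!is.null(alleles_path)) read_allele_table(alleles_path),
           traits = if (!is.null(traits_path)) read_trait_table(traits_path),
           truth = NULL)
    }
  })
  m <- fam$counts
  prog <- unique(m$samples$genotype[m$samples$role == "progeny"])

  ## --- differential expression ---------------------------------------------
  de <- stage("diffexp", {
    de <- list(PP = run_pairwise_de(m, c("P1", "P2"), config))
    for (h in prog) {
      de[[paste0("P1_", h)]] <- run_pairwise_de(m, c("P1", h), config)
      de[[paste0("P2_", h)]] <- run_pairwise_de(m, c("P2", h), config)
    }
    for (nm in names(de)) emit(de[[nm]], sprintf("de/%s.tsv", nm))
    seal()
    de
  })

  ## --- inheritance ----------------------------------------------------------
  inh <- stage("inheritance", {
    calls <- lapply(prog, function(h)
      inheritance_calls(de$PP, de[[paste0("P1_", h)]], de[[paste0("P2_", h)]], h))
    names(calls) <- prog
    all_calls <- do.call(rbind, calls)
    emit(all_calls, "inheritance/calls.tsv")
    summaries <- do.call(rbind, lapply(prog, function(h) {
      s <- summarize_inheritance(calls[[h]])
      data.frame(individual = h, t(s$counts),
                 pct_nonadditive_parent_de = s$pct_nonadditive_parent_de,
                 pct_transgressive = s$pct_transgressive)
    }))
    emit(summaries, "inheritance/summary.tsv")
    seal()
    list(calls = all_calls, summary = summaries)
  })

  ## --- regulatory divergence + dosage ---------------------------------------
  ase <- dosage <- NULL
  if (!skip_ase && !is.null(fam$alleles)) {
    dosage <- stage("dosage_cnv", {
      prof <- dosage_profiles(fam$alleles)
      emit(prof, "dosage/profiles.tsv")
      outl <- lapply(split(fam$alleles, fam$alleles$individual), function(tabi) {
        pts <- dosage_ratio_points(tabi)
        if (sum(is.finite(pts$x) & is.finite(pts$y)) >= 30)
          dosage_outliers(pts, pr = config$outlier_pr) else NULL
      })
      cum <- do.call(rbind, lapply(names(outl), function(h) {
        if (is.null(outl[[h]])) return(NULL)
        data.frame(individual = h,
                   cumulative_dysregulation =
                     cumulative_dysregulation(outl[[h]], "count",
                                              config$outlier_pr)$value)
      }))
      if (!is.null(cum)) emit(cum, "dosage/cumulative_dysregulation.tsv")
      seal()
      list(profiles = prof, outliers = outl, cumulative = cum)
    })
    ase <- stage("ase_regulatory", {
      k_map <- tapply(dosage$profiles$k, dosage$profiles$chromosome,
                      function(x) as.integer(round(stats::median(x))))
      reg <- run_regulatory_divergence(fam$alleles, config,
                                       k_by_chrom = k_map)
      emit(reg$calls, "ase/calls.tsv")
      emit(reg$summary, "ase/summary.tsv")
      seal()
      reg
    })
  }

  ## --- heterosis prediction -------------------------------------------------
  het <- NULL
  if (!is.null(fam$traits) && length(prog) >= 3) {
    het <- stage("heterosis_predict", {
      geno_cpm <- genotype_cpm(m)
      sets <- build_gene_sets(list(de$PP), geno_cpm,
                              n_random = min(5000, nrow(geno_cpm)),
                              n_top = min(5000, nrow(geno_cpm)),
                              seed = if (!is.null(sim)) sim$seed else 1L)
      z <- scale_expression(geno_cpm[, prog, drop = FALSE])
      ht <- heterosis_table(fam$traits)
      emit(ht, "heterosis/midparent_heterosis.tsv")
      emit(gene_trait_correlations(z, ht), "heterosis/gene_trait_correlations.tsv")
      reps <- cv_reps_override %||% config$cv_reps
      res <- list()
      for (tr in unique(ht$trait)) {
        y <- ht$heterosis[ht$trait == tr]
        names(y) <- ht$individual[ht$trait == tr]
        y <- y[is.finite(y)]
        for (sn in names(sets)) {
          gs <- intersect(sets[[sn]], rownames(z))
          if (length(gs) < 2) next
          fit <- nested_cv_predict(t(z[gs, names(y), drop = FALSE]), unname(y),
                                   outer = config$cv_outer,
                                   inner = config$cv_inner, reps = reps,
                                   seed = if (!is.null(sim)) sim$seed else 1L)
          res[[paste(tr, sn, sep = ".")]] <-
            data.frame(trait = tr, gene_set = sn, n_genes = length(gs),
                       r2 = fit$r2, r2_classic = fit$r2_classic)
        }
      }
      pred <- do.call(rbind, res)
      rownames(pred) <- NULL
      emit(pred, "heterosis/prediction_r2.tsv")
      seal()
      list(heterosis = ht, sets = sets, prediction = pred)
    })
  }

  ## --- manifest -------------------------------------------------------------
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$|\\.partial$", files)]
  manifest <- list(
    package = "triase",
    version = as.character(utils::packageVersion("triase")),
    thresholds = unclass(config),
    sim_seed = if (!is.null(sim)) sim$seed else NULL,
    inputs = list(counts = counts_path, alleles = alleles_path,
                  traits = traits_path),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    sub(paste0("^", outdir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(family = fam, de = de, inheritance = inh, ase = ase,
                 dosage = dosage, heterosis = het, manifest = manifest))
}
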