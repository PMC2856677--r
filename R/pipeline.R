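#' Configuration for a full pipeline run
#'
#' Collects all stage parameters and optional external inputs. When no
#' external gene sets / edge list are supplied, the network stage uses the
#' package's synthetic [toy_network_fixture()] built over the simulated
#' genes.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] driving the synthetic stage.
#' @param min_tpm,strict Expression filter parameters.
#' @param fdr_cutoff,fdr_mode,fdr_sided DE parameters (see [compute_fdr()]).
#' @param flank_bp 3'-flank window for tag classing.
#' @param pseudocount Ratio pseudocount for the network overlay.
#' @param hub Network hub/seed node.
#' @param subnetwork_radius Radius of the exported seed subnetwork.
#' @param gene_sets_path,edges_path Optional external GMT gene sets and
#'   edge-list TSV; both must exist if given.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            min_tpm = 3, strict = TRUE,
                            fdr_cutoff = 0.1, fdr_mode = "storey",
                            fdr_sided = "two",
                            flank_bp = 1000L,
                            pseudocount = 1,
                            hub = "TGFB1",
                            subnetwork_radius = 1L,
                            gene_sets_path = NULL,
                            edges_path = NULL) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop_config("missing required field: out_dir")
  if (!inherits(sim, "sim_config")) stop_config("sim must be a sim_config")
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop_config("fdr_cutoff must be in (0, 1)")
  for (p in c(gene_sets_path, edges_path)) {
    if (!is.null(p) && !file.exists(p))
      stop_config("path does not exist: ", p)
  }
  structure(list(out_dir = out_dir, sim = sim, min_tpm = min_tpm,
                 strict = strict, fdr_cutoff = fdr_cutoff,
                 fdr_mode = fdr_mode, fdr_sided = fdr_sided,
                 flank_bp = as.integer(flank_bp), pseudocount = pseudocount,
                 hub = hub, subnetwork_radius = as.integer(subnetwork_radius),
                 gene_sets_path = gene_sets_path, edges_path = edges_path),
            class = "pipeline_config")
}

# Run one stage: outputs are written under .partial names and promoted on
# success; a failure aborts with a stage-labelled error, leaving the
# .partial files for inspection.
run_stage <- function(name, out_dir, fn) {
  staged <- character(0)
  stage_write <- function(final, writer) {
    tmp <- paste0(final, ".partial")
    writer(tmp)
    staged[[length(staged) + 1L]] <<- final
    tmp
  }
  res <- tryCatch(fn(stage_write),
                  error = function(e) {
                    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
                         call. = FALSE)
                  })
  for (f in staged) file.rename(paste0(f, ".partial"), f)
  res
}

#' Run the full MPSS differential-expression pipeline
#'
#' Executes simulate -> extract/map -> quantify -> DE -> network -> report
#' on a synthetic experiment, writing every intermediate table under
#' `config$out_dir` together with a parameter manifest. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run report: a list with mapping fractions,
#'   expressed-tag count, DE tag/gene counts by direction, tags-per-gene
#'   and the abundance histogram.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim

  # --- simulate -------------------------------------------------------
  simres <- run_stage("simulate", out, function(stage_write) {
    txome <- generate_transcriptome(sim)
    truth <- simulate_expression(txome, sim)
    libs <- simulate_mpss_libraries(txome, truth, sim)
    stage_write(file.path(out, "transcriptome.fasta"), function(tmp) {
      tmp2 <- paste0(file.path(out, "annotation.tsv"), ".partial")
      write_transcriptome(txome, tmp, tmp2)
    })
    # annotation.tsv.partial written above; register for promotion
    stage_write(file.path(out, "annotation.tsv"), function(tmp) invisible(tmp))
    stage_write(file.path(out, "ground_truth.tsv"), function(tmp)
      write_tsv(as.data.frame(truth), tmp))
    write_library_set(libs, file.path(out, "libraries"))
    list(txome = txome, truth = truth, libs = libs)
  })

  # --- tags: signature db, mapping ------------------------------------
  tagres <- run_stage("tags", out, function(stage_write) {
    db <- build_signature_database(simres$txome, sim$signature_length,
                                   config$flank_bp)
    obs_tags <- sort(unique(unlist(lapply(simres$libs,
                                          function(l) names(l$counts)))))
    mapped <- map_and_classify(obs_tags, db)
    tot_count <- Reduce(`+`, lapply(simres$libs, function(l) {
      v <- l$counts[obs_tags]
      v[is.na(v)] <- 0
      as.numeric(v)
    }))
    summ <- mapping_summary(mapped, weights = tot_count)
    stage_write(file.path(out, "mapped_tags.tsv"), function(tmp)
      write_tsv(mapped, tmp))
    list(db = db, mapped = mapped, summary = summ)
  })

  # --- quantify + DE --------------------------------------------------
  deres <- run_stage("de", out, function(stage_write) {
    de <- mpss_de(simres$libs, conditions = sim$conditions,
                  min_tpm = config$min_tpm, strict = config$strict,
                  cutoff = config$fdr_cutoff, mode = config$fdr_mode,
                  sided = config$fdr_sided)
    tag2gene <- tagres$mapped[, c("tag", "gene_id")]
    genes <- rollup_genes(de$fdr, tag2gene)
    cls <- tagres$mapped$tag_class[match(de$fdr$tag, tagres$mapped$tag)]
    e1 <- de$expression[[1L]]; e2 <- de$expression[[2L]]
    de_table <- data.frame(
      tag = de$fdr$tag,
      gene_id = tag2gene$gene_id[match(de$fdr$tag, tag2gene$tag)],
      class = as.character(cls),
      tpm_tumor = e1$tpm[match(de$fdr$tag, e1$tag)],
      tpm_normal = e2$tpm[match(de$fdr$tag, e2$tag)],
      z = de$fdr$z, p = de$fdr$p, p_emp = de$fdr$p_emp,
      pi0 = de$fdr$pi0, fdr = de$fdr$fdr, called = de$fdr$called,
      stringsAsFactors = FALSE)
    de_table$tpm_tumor[is.na(de_table$tpm_tumor)] <- 0
    de_table$tpm_normal[is.na(de_table$tpm_normal)] <- 0
    stage_write(file.path(out, "de_table.tsv"), function(tmp)
      write_tsv(de_table, tmp))
    stage_write(file.path(out, "gene_table.tsv"), function(tmp)
      write_tsv(genes, tmp))
    list(de = de, genes = genes, de_table = de_table)
  })

  # --- network --------------------------------------------------------
  netres <- run_stage("network", out, function(stage_write) {
    if (!is.null(config$edges_path)) {
      edges <- read_edge_list(config$edges_path)
      sets <- read_gene_sets(config$gene_sets_path)
    } else {
      fix <- toy_network_fixture(unique(stats::na.omit(tagres$mapped$gene_id)),
                                 hub = config$hub, seed = sim$seed)
      edges <- fix$edges
      sets <- fix$gene_sets
    }
    gs <- merge_gene_sets(sets)
    flags <- intersect_with_degs(gs, deres$genes, config$fdr_cutoff)
    g <- overlay_graph(edges, nodes = gs$gene)
    tpm_t <- gene_tpm(deres$de$expression[[1L]], tagres$mapped)
    tpm_n <- gene_tpm(deres$de$expression[[2L]], tagres$mapped)
    g <- overlay_ratios(g, tpm_t, tpm_n, flags, config$pseudocount)
    sub <- extract_subnetwork(g, config$hub, config$subnetwork_radius)
    stage_write(file.path(out, "network.sif"), function(tmp) {
      tmp2 <- paste0(file.path(out, "network_attrs.tsv"), ".partial")
      export_graph(g, tmp, tmp2)
    })
    stage_write(file.path(out, "network_attrs.tsv"), function(tmp) invisible(tmp))
    stage_write(file.path(out, "subnetwork.sif"), function(tmp) {
      tmp2 <- paste0(file.path(out, "subnetwork_attrs.tsv"), ".partial")
      export_graph(sub, tmp, tmp2)
    })
    stage_write(file.path(out, "subnetwork_attrs.tsv"), function(tmp) invisible(tmp))
    list(graph = g, subnetwork = sub, flags = flags)
  })

  # --- report ---------------------------------------------------------
  run_stage("report", out, function(stage_write) {
    e1 <- deres$de$expression[[1L]]
    e2 <- deres$de$expression[[2L]]
    expressed <- filter_expressed(e1, e2, config$min_tpm, config$strict)
    hist1 <- abundance_distribution(e1)
    tpg <- tags_per_gene(tagres$mapped)
    dirs <- table(factor(deres$genes$direction[deres$genes$gene_de],
                         levels = c("up", "down", "conflict")))
    report <- list(
      conditions = sim$conditions,
      seed = sim$seed,
      n_libraries = length(simres$libs),
      mapping_summary = tagres$summary,
      n_expressed_tags = length(expressed),
      n_tags_tested = nrow(deres$de$fdr),
      n_tags_called = length(deres$de$called),
      n_genes_de = sum(deres$genes$gene_de),
      n_genes_up = unname(dirs["up"]),
      n_genes_down = unname(dirs["down"]),
      n_genes_conflict = unname(dirs["conflict"]),
      tags_per_gene = tpg$tags_per_gene,
      fraction_below_20tpm = hist1$fraction_below,
      abundance_histogram = hist1$histogram,
      n_network_nodes = igraph::vcount(netres$graph),
      n_subnetwork_nodes = igraph::vcount(netres$subnetwork))

    stage_write(file.path(out, "report.tsv"), function(tmp) {
      scal <- report[!vapply(report, is.data.frame, TRUE)]
      scal <- lapply(scal, function(x) {
        if (is.numeric(x)) paste(sprintf("%.10g", x), collapse = ",")
        else paste(as.character(x), collapse = ",")
      })
      write_tsv(data.frame(key = names(scal),
                           value = unlist(scal, use.names = FALSE),
                           stringsAsFactors = FALSE), tmp)
    })
    stage_write(file.path(out, "manifest.tsv"), function(tmp) {
      pars <- c(config[setdiff(names(config),
                               c("sim", "out_dir", "gene_sets_path",
                                 "edges_path"))],
                sim[setdiff(names(sim), "conditions")])
      write_tsv(data.frame(parameter = names(pars),
                           value = vapply(pars, function(x)
                             paste(format(x), collapse = ","), ""),
                           stringsAsFactors = FALSE), tmp)
    })
    invisible(report)
  })
}
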