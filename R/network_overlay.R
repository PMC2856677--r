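#' Merge named gene sets with evidence provenance
#'
#' Union of several evidence sets (e.g. protein-interaction partners,
#' microarray-derived regulated genes, ChIP-derived targets). Symbols are
#' uppercased and deduplicated within a set; a gene appearing in several
#' sets keeps all its evidence labels.
#'
#' @param collection Named list of character vectors of gene symbols.
#' @return data.frame(gene, evidence) with evidence as a ";"-joined label
#'   string, sorted by gene.
#' @export
merge_gene_sets <- function(collection) {
  if (length(collection) == 0L) stop_degenerate("empty gene-set collection")
  if (is.null(names(collection)) || any(names(collection) == ""))
    stop_input("all gene sets must be named")
  long <- do.call(rbind, lapply(names(collection), function(nm) {
    g <- unique(toupper(collection[[nm]]))
    if (length(g) == 0L) return(NULL)
    data.frame(gene = g, set = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) stop_degenerate("all gene sets are empty")
  ev <- tapply(long$set, long$gene, function(s) paste(sort(unique(s)), collapse = ";"))
  data.frame(gene = sort(names(ev)), evidence = as.character(ev[sort(names(ev))]),
             stringsAsFactors = FALSE)
}

#' Build an overlay graph from an interaction edge list
#'
#' Undirected graph over uppercased gene symbols; duplicate edges are
#' collapsed with their relation labels merged. Self-loops are kept only if
#' present in the input.
#'
#' @param edges data.frame with columns from, relation, to (relation
#'   optional, default "interaction").
#' @param nodes Optional extra node names to include even if isolated.
#' @return An [igraph::graph] ("overlay graph").
#' @export
overlay_graph <- function(edges, nodes = NULL) {
  if (is.null(edges$relation)) edges$relation <- rep("interaction", nrow(edges))
  if (nrow(edges)) {
    a <- toupper(edges$from)
    b <- toupper(edges$to)
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    rel <- tapply(edges$relation, key,
                  function(r) paste(sort(unique(r)), collapse = ";"))
    uk <- sort(names(rel))
    parts <- strsplit(uk, "\r", fixed = TRUE)
    el <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
    rel <- as.character(rel[uk])
  } else {
    el <- matrix(character(0), 0L, 2L)
    rel <- character(0)
  }
  verts <- sort(unique(c(el[, 1L], el[, 2L], toupper(nodes %||% character(0)))))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L], relation = rel,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Flag network genes that are differentially expressed
#'
#' Joins a merged gene set against a gene-level DE table: genes whose
#' minimum tag FDR is below the cutoff are flagged; genes absent from the
#' DE table are retained unflagged with missing FDR.
#'
#' @param gene_set A [merge_gene_sets()] result (columns gene, evidence).
#' @param gene_table A [rollup_genes()] result (gene_id, min_fdr).
#' @param cutoff FDR threshold (strict `<`), default 0.1.
#' @return data.frame(gene, evidence, min_fdr, de_flag).
#' @export
intersect_with_degs <- function(gene_set, gene_table, cutoff = 0.1) {
  i <- match(gene_set$gene, toupper(gene_table$gene_id))
  min_fdr <- gene_table$min_fdr[i]
  de_flag <- !is.na(min_fdr) & min_fdr < cutoff
  data.frame(gene = gene_set$gene, evidence = gene_set$evidence,
             min_fdr = min_fdr, de_flag = de_flag, stringsAsFactors = FALSE)
}

#' Gene-level tpm from tag-level expression
#'
#' A gene's expression is the sum of tpm over its class 1-5 tags (the
#' reliable annotation classes); used to colour network nodes by
#' tumour/normal ratio.
#'
#' @param expr An `expression_table`.
#' @param mapped A [map_and_classify()] result.
#' @return data.frame(gene_id, tpm).
#' @export
gene_tpm <- function(expr, mapped) {
  keep <- mapped$tag_class %in% c("1", "2", "3", "4", "5") & !is.na(mapped$gene_id)
  m <- mapped[keep, c("tag", "gene_id")]
  tpm <- expr$tpm[match(m$tag, expr$tag)]
  tpm[is.na(tpm)] <- 0
  s <- rowsum(tpm, m$gene_id)
  data.frame(gene_id = rownames(s), tpm = s[, 1L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Overlay expression ratios and DE flags onto a graph
#'
#' Sets per-node attributes: `log2_ratio = log2((tpm_tumor + c) /
#' (tpm_normal + c))` with pseudocount `c` (positive = over-expressed in
#' tumour), `de_flag`, and `evidence`. Nodes absent from both tpm tables
#' keep a missing ratio; a gene quantified in either condition treats the
#' missing side as zero.
#'
#' @param graph An [overlay_graph()].
#' @param tpm_tumor,tpm_normal data.frames (gene_id, tpm), e.g. from
#'   [gene_tpm()].
#' @param flags Optional [intersect_with_degs()] result supplying de_flag
#'   and evidence.
#' @param pseudocount Ratio pseudocount, default 1.
#' @return The graph with node attributes set.
#' @export
overlay_ratios <- function(graph, tpm_tumor, tpm_normal, flags = NULL,
                           pseudocount = 1) {
  v <- igraph::V(graph)$name
  tt <- tpm_tumor$tpm[match(v, toupper(tpm_tumor$gene_id))]
  tn <- tpm_normal$tpm[match(v, toupper(tpm_normal$gene_id))]
  known <- !(is.na(tt) & is.na(tn))
  tt[is.na(tt)] <- 0
  tn[is.na(tn)] <- 0
  ratio <- ifelse(known, log2((tt + pseudocount) / (tn + pseudocount)),
                  NA_real_)
  graph <- igraph::set_vertex_attr(graph, "log2_ratio", value = ratio)
  de <- rep(FALSE, length(v))
  ev <- rep(NA_character_, length(v))
  if (!is.null(flags)) {
    i <- match(v, flags$gene)
    de <- !is.na(i) & flags$de_flag[i] %in% TRUE
    ev <- flags$evidence[i]
  }
  graph <- igraph::set_vertex_attr(graph, "de_flag", value = de)
  igraph::set_vertex_attr(graph, "evidence", value = ev)
}

#' Extract a seed-centred subnetwork
#'
#' Induced subgraph of all nodes within `radius` edges (breadth-first) of
#' any seed node, e.g. the first-neighbour subnetwork around TGFB1.
#'
#' @param graph An overlay graph.
#' @param seeds Character vector of seed node names (must exist).
#' @param radius Neighbourhood radius in edges, default 1 (0 = seeds only).
#' @return The induced subgraph.
#' @export
extract_subnetwork <- function(graph, seeds, radius = 1L) {
  seeds <- toupper(seeds)
  missing <- setdiff(seeds, igraph::V(graph)$name)
  if (length(missing))
    stop_input("seed node(s) not in graph: ", paste(missing, collapse = ", "))
  hoods <- igraph::ego(graph, order = radius, nodes = seeds)
  keep <- sort(unique(unlist(lapply(hoods, function(h) h$name))))
  igraph::induced_subgraph(graph, keep)
}

#' Export an overlay graph to SIF + node-attribute files
#'
#' Writes a Cytoscape-style SIF edge file (`nodeA<TAB>relation<TAB>nodeB`,
#' no header — the SIF format carries none) and a tab-delimited
#' node-attribute table (gene, log2_ratio, de_flag, evidence) with a header.
#' Output is canonically sorted and numeric attributes are printed with
#' `%.10g`, so export -> [import_graph()] -> export round-trips byte for
#' byte.
#'
#' @param graph An overlay graph.
#' @param sif_path,attr_path Output paths.
#' @return Invisibly, the two paths.
#' @export
export_graph <- function(graph, sif_path, attr_path) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(ed)) {
    lo <- pmin(ed$from, ed$to)
    hi <- pmax(ed$from, ed$to)
    rel <- if (!is.null(ed$relation)) ed$relation else rep("interaction", nrow(ed))
    lines <- sort(paste(lo, rel, hi, sep = "\t"))
  } else lines <- character(0)
  writeLines(lines, sif_path)

  v <- sort(igraph::V(graph)$name)
  g <- igraph::as_data_frame(graph, what = "vertices")
  i <- match(v, g$name)
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  ratio <- if (!is.null(g$log2_ratio)) g$log2_ratio[i] else rep(NA_real_, length(v))
  de <- if (!is.null(g$de_flag)) g$de_flag[i] %in% TRUE else rep(FALSE, length(v))
  ev <- if (!is.null(g$evidence)) g$evidence[i] else rep(NA_character_, length(v))
  writeLines(c("gene\tlog2_ratio\tde_flag\tevidence",
               if (length(v)) paste(v, fmt_num(ratio), de,
                                    ifelse(is.na(ev), "NA", ev), sep = "\t")),
             attr_path)
  invisible(c(sif = sif_path, attr = attr_path))
}

#' Import an overlay graph from SIF + node-attribute files
#'
#' Inverse of [export_graph()].
#'
#' @param sif_path,attr_path Input paths.
#' @return An overlay graph with node attributes restored.
#' @export
import_graph <- function(sif_path, attr_path) {
  sif <- readLines(sif_path)
  sif <- sif[nzchar(sif)]
  if (length(sif)) {
    parts <- strsplit(sif, "\t", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        relation = vapply(parts, `[`, "", 2L),
                        to = vapply(parts, `[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), relation = character(0),
                        to = character(0), stringsAsFactors = FALSE)
  }
  at <- utils::read.delim(attr_path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  g <- overlay_graph(edges, nodes = at$gene)
  i <- match(igraph::V(g)$name, at$gene)
  g <- igraph::set_vertex_attr(g, "log2_ratio", value = as.numeric(at$log2_ratio[i]))
  g <- igraph::set_vertex_attr(g, "de_flag", value = at$de_flag[i] %in% TRUE)
  igraph::set_vertex_attr(g, "evidence", value = as.character(at$evidence[i]))
}

#' Toy TGF-beta-style network fixture
#'
#' Generates a small interaction edge list and evidence gene sets around a
#' hub node from a supplied gene universe, for exercising the network
#' overlay without any database retrieval. Synthetic by construction.
#'
#' @param gene_ids Character vector of available gene symbols.
#' @param hub Hub node name, default "TGFB1".
#' @param n_partners,n_regulated,n_targets Sizes of the three evidence sets
#'   (capped at the universe size).
#' @param seed RNG seed.
#' @return List with `edges` (from, relation, to) and `gene_sets` (named
#'   list).
#' @export
toy_network_fixture <- function(gene_ids, hub = "TGFB1", n_partners = 20L,
                                n_regulated = 40L, n_targets = 10L,
                                seed = 1L) {
  set.seed(seed)
  gene_ids <- unique(toupper(gene_ids))
  pick <- function(n) sample(gene_ids, min(n, length(gene_ids)))
  partners <- pick(n_partners)
  regulated <- pick(n_regulated)
  targets <- pick(n_targets)
  edges <- rbind(
    data.frame(from = hub, relation = "interaction", to = partners,
               stringsAsFactors = FALSE),
    data.frame(from = hub, relation = "regulated-by", to = regulated,
               stringsAsFactors = FALSE),
    data.frame(from = sample(partners, min(5L, length(partners))),
               relation = "chip-target",
               to = sample(targets, min(5L, length(targets))),
               stringsAsFactors = FALSE))
  list(edges = edges,
       gene_sets = list(interaction_partners = partners,
                        microarray_regulated = regulated,
                        chip_targets = targets))
}
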