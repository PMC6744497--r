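# Gene-level linkage of differential methylation to differential expression:
# probe-to-gene mapping, per-gene DMC rollups, promoter/gene-body direction
# concordance, and the candidate filter (>= 2 CpGs with |delta-beta| above
# threshold).

#' Map probes to genes via the manifest
#'
#' A probe annotated to k gene symbols is listed under all k genes;
#' intergenic probes map to no gene. No distance window is applied: the
#' manifest's gene annotation is the only linkage used.
#'
#' @param ann Probe annotation (see [read_annotation()]).
#' @return Named list: gene id -> character vector of probe ids.
#' @export
map_probes_to_genes <- function(ann) {
  genes <- split_gene_symbols(ann$gene_symbols)
  k <- lengths(genes)
  if (sum(k) == 0L) return(stats::setNames(list(), character()))
  split(rep(ann$probe_id, k), unlist(genes))
}

#' Per-gene rollup of significant methylation changes
#'
#' Expands significant probes of a methylation differential table to their
#' annotated genes and summarizes the evidence per gene. Multi-gene probes
#' contribute one link per gene, so link totals can exceed the number of
#' unique probes; both totals are reported.
#'
#' @param dm Methylation differential table ([diff_methylation()]), computed
#'   on QC-passed probes.
#' @param ann Probe annotation covering the tested probes.
#' @param gene_universe Optional character vector (e.g. differentially
#'   expressed genes at the same timepoint) to which the `n_genes` total is
#'   restricted; links themselves are not filtered.
#' @return List with `genes` (data.frame `gene_id, n_dmc,
#'   max_abs_delta_beta`), `links` (data.frame `gene_id, probe_id,
#'   delta_beta_pp, q, region_feature, zone`), and `totals` (list
#'   `n_links, n_unique_probes, n_genes`).
#' @export
summarize_gene_methylation <- function(dm, ann, gene_universe = NULL) {
  sig <- dm[dm$significant, , drop = FALSE]
  a <- ann[match(sig$feature, ann$probe_id), , drop = FALSE]
  if (anyNA(a$probe_id) && nrow(sig) > 0L) {
    stop("significant probes missing from annotation")
  }
  genes <- split_gene_symbols(a$gene_symbols)
  k <- lengths(genes)
  links <- data.frame(
    gene_id = unlist(genes),
    probe_id = rep(sig$feature, k),
    delta_beta_pp = rep(sig$effect, k),
    q = rep(sig$q, k),
    region_feature = rep(a$region_feature, k),
    stringsAsFactors = FALSE, row.names = NULL)
  links$zone <- region_3way(links$region_feature)
  if (nrow(links) > 0L) {
    gene_tab <- do.call(rbind, lapply(split(links, links$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1L], n_dmc = nrow(g),
                 max_abs_delta_beta = max(abs(g$delta_beta_pp)),
                 stringsAsFactors = FALSE)
    }))
    rownames(gene_tab) <- NULL
  } else {
    gene_tab <- data.frame(gene_id = character(), n_dmc = integer(),
                           max_abs_delta_beta = numeric(), stringsAsFactors = FALSE)
  }
  n_genes <- if (is.null(gene_universe)) nrow(gene_tab) else
    length(intersect(gene_tab$gene_id, gene_universe))
  list(genes = gene_tab, links = links,
       totals = list(n_links = nrow(links),
                     n_unique_probes = length(unique(links$probe_id)),
                     n_genes = n_genes))
}

#' Methylation-expression direction concordance per gene
#'
#' For each significantly differentially expressed gene, each of its
#' significant CpGs is scored as consistent when (gene up and promoter CpG
#' hypomethylated), (gene up and gene-body CpG hypermethylated), or the
#' mirrored patterns for downregulated genes. Gene classes: all CpGs
#' consistent gives `concordant_promoter` or `concordant_body` (by the zone
#' contributing most consistent CpGs, ties to promoter), none consistent
#' gives `discordant`, a mixture gives `mixed`, and no linked CpG gives
#' `unlinked`.
#'
#' @param de Expression differential table for the same contrast; only its
#'   significant genes are classified.
#' @param summaries Result of [summarize_gene_methylation()].
#' @param ann Probe annotation (defines the gene universe; a significant gene
#'   absent from the manifest's gene vocabulary is an error).
#' @param promoter_zone,body_zone Region features treated as promoter / gene
#'   body.
#' @return data.frame: `gene_id, expr_direction, class, n_probes,
#'   n_consistent`.
#' @export
concordance <- function(de, summaries, ann,
                        promoter_zone = PROMOTER_FEATURES,
                        body_zone = BODY_FEATURES) {
  degs <- de[de$significant, , drop = FALSE]
  gene_universe <- unique(unlist(split_gene_symbols(ann$gene_symbols)))
  missing <- setdiff(degs$feature, gene_universe)
  if (length(missing) > 0L) {
    stop("differentially expressed gene(s) absent from the annotation gene ",
         "universe: ", paste(utils::head(missing, 10L), collapse = ", "))
  }
  links <- summaries$links
  out <- lapply(seq_len(nrow(degs)), function(i) {
    g <- degs$feature[i]
    dir_up <- degs$direction[i] == "up"
    lk <- links[links$gene_id == g, , drop = FALSE]
    zone <- ifelse(lk$region_feature %in% promoter_zone, "promoter",
                   ifelse(lk$region_feature %in% body_zone, "body", "other"))
    hypo <- lk$delta_beta_pp < 0
    consistent <- (zone == "promoter" & (hypo == dir_up)) |
      (zone == "body" & (hypo != dir_up))
    cls <- if (nrow(lk) == 0L) "unlinked"
    else if (all(consistent)) {
      zc <- table(zone[consistent])
      if ((zc["promoter"] %||% 0L) >= (zc["body"] %||% 0L)) "concordant_promoter"
      else "concordant_body"
    } else if (!any(consistent)) "discordant" else "mixed"
    data.frame(gene_id = g, expr_direction = degs$direction[i], class = cls,
               n_probes = nrow(lk), n_consistent = sum(consistent),
               stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(gene_id = character(), expr_direction = character(),
               class = character(), n_probes = integer(),
               n_consistent = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Candidate genes with robust methylation-expression coupling
#'
#' Selects differentially expressed, methylation-linked genes carrying at
#' least `min_cpgs` significant CpGs of which at least `min_cpgs` exceed
#' `min_abs_delta_beta_pp` in absolute delta-beta. Ordered by decreasing
#' maximal |delta-beta|, ties broken by gene id.
#'
#' @param summaries Result of [summarize_gene_methylation()].
#' @param concordance_records Result of [concordance()]; only genes with at
#'   least one linked CpG (class other than `unlinked`) are eligible.
#' @param min_cpgs Minimum number of significant CpGs (default 2).
#' @param min_abs_delta_beta_pp Minimum |delta-beta| in percentage points
#'   (default 5, exclusive).
#' @return data.frame: `gene_id, n_dmc, n_dmc_above_threshold,
#'   max_abs_delta_beta, class`.
#' @export
candidate_filter <- function(summaries, concordance_records,
                             min_cpgs = 2L, min_abs_delta_beta_pp = 5) {
  linked <- concordance_records[concordance_records$class != "unlinked", ,
                                drop = FALSE]
  links <- summaries$links
  rows <- lapply(linked$gene_id, function(g) {
    lk <- links[links$gene_id == g, , drop = FALSE]
    above <- sum(abs(lk$delta_beta_pp) > min_abs_delta_beta_pp)
    if (nrow(lk) >= min_cpgs && above >= min_cpgs) {
      data.frame(gene_id = g, n_dmc = nrow(lk), n_dmc_above_threshold = above,
                 max_abs_delta_beta = max(abs(lk$delta_beta_pp)),
                 class = linked$class[linked$gene_id == g][1L],
                 stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  res <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), n_dmc = integer(),
               n_dmc_above_threshold = integer(), max_abs_delta_beta = numeric(),
               class = character(), stringsAsFactors = FALSE)
  res <- res[order(-res$max_abs_delta_beta, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
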