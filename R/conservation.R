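#' Gene-by-species detection matrix
#'
#' @param per_species_lists named list mapping each species to its combined
#'   dynamic gene list (reference symbols).
#' @return logical matrix, union of genes x species.
#' @export
detection_matrix <- function(per_species_lists) {
  species <- names(per_species_lists)
  genes <- sort(unique(unlist(per_species_lists)))
  det <- matrix(FALSE, length(genes), length(species),
                dimnames = list(genes, species))
  for (s in species) det[per_species_lists[[s]], s] <- TRUE
  det
}

#' Sharing classification of detected genes
#'
#' Genes detected in every species are `high_shared` and additionally flagged
#' as evolutionary core; detection in at least `high_min` species is
#' `high_shared`; 2 up to `high_min - 1` species is `intermediate_shared`;
#' one species is `species_restricted`.
#'
#' @param detections logical gene-by-species matrix.
#' @param high_min species count defining `high_shared` (default 4).
#' @return data frame with `gene`, `n_species`, `share_class`, `is_core`.
#' @export
classify_sharing <- function(detections, high_min = 4) {
  n <- rowSums(detections)
  n_species <- ncol(detections)
  share_class <- ifelse(n >= high_min, "high_shared",
                        ifelse(n >= 2, "intermediate_shared",
                               ifelse(n == 1, "species_restricted", "none")))
  data.frame(gene = rownames(detections), n_species = as.integer(n),
             share_class = share_class, is_core = n == n_species,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Clade-exclusive classification
#'
#' A gene is `amniote_exclusive` when detected in every amniote species and
#' in no teleost, `teleost_exclusive` in the mirror case; genes detected in
#' all species (core) are neither; any other detected gene is `mixed`;
#' undetected genes are `none`.
#'
#' @param detections logical gene-by-species matrix.
#' @param clade_partition named character vector species -> clade.
#' @return character vector of clade classes, named by gene.
#' @export
clade_exclusive <- function(detections, clade_partition) {
  species <- colnames(detections)
  missing <- setdiff(species, names(clade_partition))
  if (length(missing) > 0)
    stop("clade partition missing species: ", paste(missing, collapse = ", "))
  amn <- species[clade_partition[species] == "amniote"]
  tel <- species[clade_partition[species] == "teleost"]
  n <- rowSums(detections)
  all_amn <- rowSums(detections[, amn, drop = FALSE]) == length(amn)
  any_amn <- rowSums(detections[, amn, drop = FALSE]) > 0
  all_tel <- rowSums(detections[, tel, drop = FALSE]) == length(tel)
  any_tel <- rowSums(detections[, tel, drop = FALSE]) > 0
  cls <- ifelse(n == 0, "none",
                ifelse(n == ncol(detections), "none",  # core genes are neither
                       ifelse(all_amn & !any_tel, "amniote_exclusive",
                              ifelse(all_tel & !any_amn, "teleost_exclusive", "mixed"))))
  stats::setNames(cls, rownames(detections))
}

#' Modal stage assignment per gene and group stage proportions
#'
#' Each detecting species contributes the stage in which the gene passed the
#' DEG filters (when a gene passes in several stages within one species, the
#' stage with the largest log2 fold change is taken). The gene is assigned
#' the modal stage across detecting species, ties broken by developmental
#' order (OPC, then COP, then MOL).
#'
#' @param deg_records combined DEG data frame across species.
#' @param gene_groups optional named list of gene sets (e.g. core /
#'   amniote-exclusive / teleost-exclusive) for which stage proportions are
#'   tabulated.
#' @return list with `per_gene` (gene, stage) and `group_proportions`.
#' @export
stage_enrichment_assignment <- function(deg_records, gene_groups = NULL) {
  if (nrow(deg_records) == 0) stop("no DEG records supplied")
  # one stage per (gene, species): max |log2fc|
  key <- paste(deg_records$gene, deg_records$species)
  best <- deg_records[order(key, -abs(deg_records$log2fc)), ]
  best <- best[!duplicated(paste(best$gene, best$species)), ]
  per_gene <- do.call(rbind, lapply(split(best, best$gene), function(d) {
    counts <- table(factor(d$stage, levels = .stage_levels))
    data.frame(gene = d$gene[1],
               stage = .stage_levels[which.max(counts)],  # tie -> earliest stage
               n_detecting = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  group_proportions <- NULL
  if (!is.null(gene_groups)) {
    group_proportions <- do.call(rbind, lapply(names(gene_groups), function(g) {
      sub <- per_gene[per_gene$gene %in% gene_groups[[g]], ]
      if (nrow(sub) == 0) {
        warning("gene group '", g, "' has no stage-assigned genes")
        return(NULL)
      }
      p <- prop.table(table(factor(sub$stage, levels = .stage_levels)))
      data.frame(group = g, stage = names(p), proportion = as.numeric(p),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_gene = per_gene, group_proportions = group_proportions)
}

#' Species-combination intersection counts (UpSet-style)
#'
#' Tallies genes by their exact detection pattern across species.
#'
#' @param detections logical gene-by-species matrix.
#' @return data frame with `pattern` (semicolon-joined species labels),
#'   `n_species`, `count`, covering every observed nonzero pattern.
#' @export
intersection_counts <- function(detections) {
  n <- rowSums(detections)
  det <- detections[n > 0, , drop = FALSE]
  if (nrow(det) == 0)
    return(data.frame(pattern = character(0), n_species = integer(0),
                      count = integer(0)))
  pat <- apply(det, 1, function(r) paste(colnames(det)[r], collapse = ";"))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab),
                    n_species = lengths(strsplit(names(tab), ";", fixed = TRUE)),
                    count = as.integer(tab), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$pattern), ]
}

#' Hypergeometric over-representation test with BH correction
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least the overlap between the gene set and the term within
#' the universe; p-values are Benjamini-Hochberg adjusted across terms. The
#' reported `q_value` equals the BH-adjusted p.
#'
#' @param gene_set character vector, must be a subset of `universe`.
#' @param universe character vector of testable genes.
#' @param annotation_table data frame with columns `term` and `gene`.
#' @param alpha BH-adjusted p threshold for the `significant` flag.
#' @param q_max q-value threshold for the `significant` flag.
#' @return data frame per term: `term`, `k` (overlap), `K` (term size in
#'   universe), `n` (set size), `N` (universe size), `p_value`, `p_bh`,
#'   `significant`.
#' @export
hypergeom_enrichment <- function(gene_set, universe, annotation_table,
                                 alpha = 0.05, q_max = 0.1) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0)
    stop("gene set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  stopifnot(all(c("term", "gene") %in% names(annotation_table)))
  N <- length(universe)
  n <- length(gene_set)
  terms <- split(annotation_table$gene, annotation_table$term)
  rows <- lapply(names(terms), function(tm) {
    term_genes <- intersect(unique(terms[[tm]]), universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, gene_set))
    p <- if (K == 0 || k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_bh < alpha & out$p_bh < q_max
  out[order(out$p_value), ]
}
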