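#' Construct a community table
#'
#' Bundles an OTU count matrix (samples in rows, taxa in columns) with a
#' taxon-to-phylum map. Counts must be non-negative integers; taxa missing
#' from the taxonomy are assigned to `"Unclassified"` with a warning.
#'
#' @param counts Integer matrix, samples x taxa, with row and column names.
#' @param taxonomy A data frame with columns `taxon_id` and `phylum` (a full
#'   lineage string containing a `p__Phylum` field is also accepted).
#' @return An object of class `enzlim_community`.
#' @seealso [read_otu_table()], [phylum_abundance()], [diversity_table()]
#' @export
community_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs sample row names and taxon column names.",
          class = "enzlim_schema_error")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("duplicated sample or taxon ids in `counts`.",
          class = "enzlim_schema_error")
  }
  if (any(counts < 0)) {
    abort("negative counts are not allowed.", class = "enzlim_domain_error")
  }
  if (any(counts != round(counts))) {
    abort("counts must be integers.", class = "enzlim_domain_error")
  }
  storage.mode(counts) <- "integer"
  taxonomy <- tibble::as_tibble(taxonomy)
  if (!all(c("taxon_id", "phylum") %in% names(taxonomy))) {
    abort("`taxonomy` needs columns taxon_id and phylum.",
          class = "enzlim_schema_error")
  }
  if (anyDuplicated(taxonomy$taxon_id)) {
    abort("duplicated taxon_id in taxonomy.", class = "enzlim_schema_error")
  }
  taxonomy$phylum <- parse_phylum(taxonomy$phylum)
  missing <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(missing) > 0) {
    warn(paste0(length(missing),
                " taxa absent from taxonomy mapped to 'Unclassified'."))
    taxonomy <- dplyr::bind_rows(
      taxonomy,
      tibble::tibble(taxon_id = missing, phylum = "Unclassified")
    )
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ]
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " sample(s) have zero total counts; they are ",
                "retained but dropped by rarefaction and dissimilarity."))
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "enzlim_community")
}

# Accepts either a bare phylum name or a lineage string with a p__ field.
parse_phylum <- function(x) {
  x <- as.character(x)
  has_lineage <- grepl("p__", x)
  x[has_lineage] <- sub("^.*p__([^;|]*).*$", "\\1", x[has_lineage])
  x <- trimws(x)
  x[is.na(x) | x == ""] <- "Unclassified"
  x
}

#' @export
print.enzlim_community <- function(x, ...) {
  cat("<enzlim_community> ", nrow(x$counts), " samples x ",
      ncol(x$counts), " taxa, ",
      length(unique(x$taxonomy$phylum)), " phyla\n", sep = "")
  invisible(x)
}

#' @export
dim.enzlim_community <- function(x) dim(x$counts)

#' @importFrom tibble as_tibble
#' @method as_tibble enzlim_community
#' @export
as_tibble.enzlim_community <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(long) <- c("sample_id", "taxon_id", "count")
  long$count <- as.integer(long$count)
  dplyr::left_join(long, x$taxonomy, by = "taxon_id")
}

community_counts <- function(x) {
  if (inherits(x, "enzlim_community")) x$counts else as.matrix(x)
}

#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, where `p_i`
#' are relative abundances. Combines richness and evenness; natural
#' logarithms (nats) by ecological convention, configurable via `base`.
#'
#' @param counts Non-negative numeric vector of taxon counts with at least
#'   one positive entry.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (scalar).
#' @examples
#' shannon_index(c(5, 5, 5, 5)) # log(4)
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0, na.rm = TRUE)) {
    abort("counts must be non-negative.", class = "enzlim_domain_error")
  }
  if (sum(counts, na.rm = TRUE) <= 0) {
    abort("all-zero count vector has no diversity.",
          class = "enzlim_domain_error")
  }
  as.numeric(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                              base = base))
}

#' Per-sample alpha diversity of a community
#'
#' @param community An [community_table()] object or a samples x taxa count
#'   matrix.
#' @param base Logarithm base for the Shannon index.
#' @return A tibble with `sample_id`, `shannon`, `richness` (taxa with
#'   positive count). Samples with zero total counts get `NA` shannon.
#' @export
diversity_table <- function(community, base = exp(1)) {
  m <- community_counts(community)
  tot <- rowSums(m)
  sh <- rep(NA_real_, nrow(m))
  sh[tot > 0] <- as.numeric(vegan::diversity(m[tot > 0, , drop = FALSE],
                                             index = "shannon", base = base))
  tibble::tibble(
    sample_id = rownames(m),
    shannon = sh,
    richness = as.integer(rowSums(m > 0))
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)`: 0 for identical
#' compositions, 1 for disjoint ones.
#'
#' @param a,b Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 2, 3), c(3, 2, 1)) # 1/3
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length.", class = "enzlim_schema_error")
  }
  if (any(c(a, b) < 0)) {
    abort("abundances must be non-negative.", class = "enzlim_domain_error")
  }
  tot <- sum(a + b)
  if (tot == 0) {
    abort("both vectors are all-zero; dissimilarity undefined.",
          class = "enzlim_domain_error")
  }
  sum(abs(a - b)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Computed on raw counts (not transformed abundances). Samples with zero
#' total counts are excluded with a warning.
#'
#' @inheritParams diversity_table
#' @return A [stats::dist] object labelled by sample id; `as.matrix()` gives
#'   the square form.
#' @export
distance_matrix <- function(community) {
  m <- community_counts(community)
  if (nrow(m) < 2) {
    abort("need at least 2 samples.", class = "enzlim_domain_error")
  }
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warn(paste0("excluding ", sum(empty), " all-zero sample(s): ",
                paste(rownames(m)[empty], collapse = ", ")))
    m <- m[!empty, , drop = FALSE]
  }
  vegan::vegdist(m, method = "bray")
}

#' Hellinger transformation of community abundances
#'
#' Each count becomes the square root of its within-sample relative
#' abundance, giving unit-norm sample rows — the standard pre-treatment
#' before Euclidean-based ordination of community data.
#'
#' @inheritParams diversity_table
#' @return A numeric matrix of the same dimensions.
#' @examples
#' hellinger(matrix(c(1, 3), nrow = 1, dimnames = list("s1", c("a", "b"))))
#' @export
hellinger <- function(community) {
  m <- community_counts(community)
  if (any(rowSums(m) == 0)) {
    abort("zero-total samples cannot be Hellinger-transformed.",
          class = "enzlim_domain_error")
  }
  as.matrix(vegan::decostand(m, method = "hellinger"))
}

#' Rarefy a community to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth so
#' that richness and diversity are comparable across uneven sequencing
#' effort. Samples with fewer reads than `depth` are dropped with a warning.
#'
#' @inheritParams diversity_table
#' @param depth Target reads per sample; default is the minimum positive
#'   sample total.
#' @param seed Integer seed making the subsample reproducible.
#' @return A rarefied `enzlim_community` (or matrix, matching the input).
#' @export
rarefy_table <- function(community, depth = NULL, seed = 1) {
  m <- community_counts(community)
  tot <- rowSums(m)
  if (is.null(depth)) depth <- min(tot[tot > 0])
  depth <- as.integer(depth)
  if (depth < 1) abort("`depth` must be >= 1.", class = "enzlim_domain_error")
  if (all(tot < depth)) {
    abort("rarefaction depth exceeds every sample's total count.",
          class = "enzlim_domain_error")
  }
  drop <- tot < depth
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " sample(s) below depth ", depth,
                ": ", paste(rownames(m)[drop], collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
  }
  rar <- with_opt_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      # vegan flags small matrices as possibly not being counts; ours are
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  storage.mode(rar) <- "integer"
  if (inherits(community, "enzlim_community")) {
    community_table(rar, community$taxonomy)
  } else {
    rar
  }
}

#' Phylum-level relative abundances
#'
#' Aggregates OTU counts to phylum level and converts to within-sample
#' relative abundances.
#'
#' @param community An [community_table()] object.
#' @return A tibble `sample_id`, `phylum`, `count`, `rel_abund` (proportion
#'   of the sample's reads).
#' @export
phylum_abundance <- function(community) {
  if (!inherits(community, "enzlim_community")) {
    abort("`community` must be an enzlim_community.",
          class = "enzlim_schema_error")
  }
  m <- community$counts
  phy <- community$taxonomy$phylum[match(colnames(m),
                                         community$taxonomy$taxon_id)]
  agg <- t(rowsum(t(m), group = phy))
  tot <- rowSums(agg)
  long <- tibble::as_tibble(as.table(agg), .name_repair = "minimal")
  names(long) <- c("sample_id", "phylum", "count")
  long$count <- as.integer(long$count)
  long$rel_abund <- unname(long$count / tot[long$sample_id])
  dplyr::arrange(long, .data$sample_id, dplyr::desc(.data$rel_abund))
}
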