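# Shared fixture builders (everything generated in code; no stored data).

# Tiny genotype panel from an explicit dosage matrix.
gmat <- function(dosage, chrom = "chr1", pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  mk <- data.frame(id = sprintf("M%03d", seq_len(m)), chrom = chrom,
                   pos = pos, ref = "A", alt = "T",
                   stringsAsFactors = FALSE)
  G <- GenotypeMatrix(dosage, mk)
  rownames(G@dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  G
}

# Balanced phenotyping design: every genotype in every block x replicate
# x water x month cell.
fullDesign <- function(ids, nBlock = 2, nRep = 2,
                       water = c("low", "high"), months = "m1") {
  expand.grid(genotype = ids, block = paste0("b", seq_len(nBlock)),
              replicate = paste0("r", seq_len(nRep)), water = water,
              month = months, stringsAsFactors = FALSE)
}

# Expression matrix with hub-and-spoke (star) correlation structure whose
# soft-thresholded connectivity follows a falling power law.
scaleFreeExpr <- function(seed, ns = 50,
                          sizes = c(50, 25, 12, 6, 6, 3, 3, 2, 2, 2)) {
  set.seed(seed)
  hubs <- matrix(rnorm(length(sizes) * ns), length(sizes), ns)
  rows <- list()
  for (m in seq_along(sizes)) {
    rows[[length(rows) + 1]] <- hubs[m, ] + 0.05 * rnorm(ns)
    for (j in seq_len(sizes[m]))
      rows[[length(rows) + 1]] <- sqrt(0.5) * hubs[m, ] +
        sqrt(0.5) * rnorm(ns)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  X
}

# Random connected simple graph on n nodes (edge prob p, resampled until
# connected), as an igraph with named vertices.
randomConnectedGraph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    am <- matrix(0, n, n)
    am[upper.tri(am)] <- rbinom(n * (n - 1) / 2, 1, p)
    am <- am + t(am)
    g <- igraph::graph_from_adjacency_matrix(am, mode = "undirected")
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("n", seq_len(n))
      return(list(graph = g, am = am))
    }
  }
}

# The printed marker statistics shipped with the package (GWAS stem
# diameter markers): id, chrom, pos, maf, effect.
gwasMarkerTable <- function() {
  read.delim(system.file("extdata", "gwas_markers_sd.tsv",
                         package = "GrowthOmics"),
             stringsAsFactors = FALSE)
}
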