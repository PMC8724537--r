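## Readers and writers for the standard plain-text formats around the
## pipeline: VCF 4.2 genotypes (via vcfR on read), phenotype / annotation
## / pathway TSVs, GFF3 annotation, and the simulation truth as JSON.

#' Read a diploid biallelic VCF into a GenotypeMatrix
#'
#' Parses the GT field (phased or unphased; `./.` missing) into alt-allele
#' dosages. Multiallelic records are dropped with a warning.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @return A [GenotypeMatrix-class] object (samples x markers).
#' @export
readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("%d multiallelic record(s) dropped", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleleCount <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_real_,
           vapply(strsplit(x, "/", fixed = TRUE),
                  function(z) sum(as.numeric(z)), numeric(1)))
  }
  dos <- t(apply(gt, 1, alleleCount))
  if (ncol(v@gt) - 1 == 1) dos <- matrix(dos, ncol = 1)
  dos <- t(dos)  # samples x markers
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  markers <- data.frame(id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, stringsAsFactors = FALSE)
  G <- GenotypeMatrix(dos, markers)
  rownames(G@dosage) <- colnames(gt)
  G
}

#' Write a GenotypeMatrix as VCF 4.2
#'
#' GT-only records; missing dosages become `./.`; dosage 1 is written as
#' the unphased heterozygote `0/1`.
#'
#' @param G [GenotypeMatrix-class].
#' @param path output path (plain text).
#' @export
writeGenotypesVcf <- function(G, path) {
  d <- dosage(G)
  mk <- markerInfo(G)
  gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  samples <- rownames(d) %||% sprintf("S%04d", seq_len(nrow(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=GrowthOmics",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", gtOf[as.character(d[, j])])
    writeLines(paste(c(mk$chrom[j], mk$pos[j], mk$id[j], mk$ref[j],
                       mk$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header `sample, genotype, block, replicate, water,
#' month, value`.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readPhenotypeTable <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  .checkPhenotypeTable(p)
}

#' Read a flat transcript annotation table
#'
#' Tab-separated with header `gene_id, chrom, start, end, strand,
#' product, GO, EC` (GO/EC `;`-separated, may be empty).
#'
#' @param path TSV file.
#' @return annotation data.frame.
#' @export
readAnnotationTable <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (any(a$start > a$end)) stop("annotation with start > end")
  for (col in c("GO", "EC")) {
    if (is.null(a[[col]])) a[[col]] <- ""
    a[[col]] <- as.character(a[[col]])
    a[[col]][is.na(a[[col]])] <- ""
  }
  a
}

#' Write / read transcript annotation as GFF3
#'
#' Gene features with `ID`, `product`, `Ontology_term` and `ec_number`
#' attributes; coordinates 1-based inclusive as per GFF3.
#'
#' @param annot annotation data.frame (see [readAnnotationTable()]).
#' @param path file path.
#' @return `writeAnnotationGff3` the path, invisibly;
#'   `readAnnotationGff3` an annotation data.frame.
#' @export
writeAnnotationGff3 <- function(annot, path) {
  attr <- paste0("ID=", annot$gene_id,
                 ";product=", gsub("[;=\t]", "_",
                                   annot$product %||% "unknown"),
                 ifelse(nzchar(annot$GO %||% ""),
                        paste0(";Ontology_term=", annot$GO), ""),
                 ifelse(nzchar(annot$EC %||% ""),
                        paste0(";ec_number=", annot$EC), ""))
  lines <- paste(annot$chrom, "GrowthOmics", "gene", annot$start,
                 annot$end, ".", annot$strand %||% "+", ".", attr,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname writeAnnotationGff3
#' @export
readAnnotationGff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  attrs <- f[, 9]
  pick <- function(key) {
    vapply(attrs, function(a) {
      m <- regmatches(a, regexpr(paste0(key, "=[^;]*"), a))
      if (length(m)) sub(paste0(key, "="), "", m) else ""
    }, "", USE.NAMES = FALSE)
  }
  data.frame(gene_id = pick("ID"), chrom = f[, 1],
             start = as.integer(f[, 4]), end = as.integer(f[, 5]),
             strand = f[, 7], product = pick("product"),
             GO = pick("Ontology_term"), EC = pick("ec_number"),
             stringsAsFactors = FALSE)
}

#' Read / write the pathway database TSV dialect
#'
#' Columns `pathway_id, reaction_id, ec, substrates, products`; compound
#' lists `;`-separated.
#'
#' @param pathways pathway data.frame.
#' @param path TSV file.
#' @return `readPathwayDb` the pathway data.frame; `writePathwayDb` the
#'   path, invisibly.
#' @export
readPathwayDb <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "reaction_id", "ec", "substrates", "products")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("pathway db lacks columns: ", paste(miss, collapse = ", "))
  p
}

#' @rdname readPathwayDb
#' @export
writePathwayDb <- function(pathways, path) {
  write.table(pathways, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a SimulationTruth as JSON
#'
#' @param truth [SimulationTruth-class].
#' @param path output JSON path.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(
    list(qtl_markers = truth@qtlMarkers,
         variance_components = as.list(truth@varianceComponents),
         module_assignment = as.list(truth@moduleAssignment),
         ld_block_map = as.list(truth@ldBlockMap),
         te_regions = truth@teRegions,
         seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
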