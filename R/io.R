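# Plain-text writers/readers for the pipeline's external interfaces:
# VCF genotypes, MSP-style local ancestry, OBJ templates, packed coordinate
# tables, and loci as BED.

#' Write a genotype panel as VCF
#'
#' Minimal VCFv4.2 with phased GT when haplotypes are available, otherwise
#' unphased genotypes reconstructed from the dosage. REF is the major
#' allele (dosage counts REF).
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @export
write_vcf <- function(panel, path) {
  n <- nrow(panel$dosage)
  ids <- sprintf("S%04d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=vaultgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  v <- panel$variants
  phased <- !is.null(panel$haplotypes)
  for (j in seq_len(nrow(v))) {
    if (phased) {
      # allele 1 = major = REF -> VCF allele index 0
      a1 <- 1L - panel$haplotypes[, j, 1L]
      a2 <- 1L - panel$haplotypes[, j, 2L]
      gt <- paste0(a1, "|", a2)
    } else {
      gt <- c("1/1", "0/1", "0/0")[panel$dosage[, j] + 1L]
    }
    writeLines(paste(c(v$chrom[j], v$bp[j], v$id[j], v$allele_major[j],
                       v$allele_minor[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF written by [write_vcf()]
#'
#' Parses GT fields (phased or unphased) into a `genotype_panel` with
#' dosage counting the REF (major) allele.
#'
#' @param path VCF file.
#' @return a `genotype_panel` (without ancestry or window information).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1L], "\t")[[1L]]
  rows <- strsplit(body[-1L], "\t")
  n <- length(header) - 9L
  s <- length(rows)
  dosage <- matrix(0L, n, s)
  haplo <- array(0L, dim = c(n, s, 2L))
  phased <- TRUE
  v <- data.frame(chrom = integer(s), bp = integer(s), id = character(s),
                  allele_major = character(s), allele_minor = character(s),
                  maf = NA_real_)
  for (j in seq_len(s)) {
    r <- rows[[j]]
    v$chrom[j] <- as.integer(r[1L]); v$bp[j] <- as.integer(r[2L])
    v$id[j] <- r[3L]; v$allele_major[j] <- r[4L]; v$allele_minor[j] <- r[5L]
    gt <- r[-(1:9)]
    phased <- phased && all(grepl("|", gt, fixed = TRUE))
    al <- matrix(as.integer(unlist(strsplit(gt, "[|/]"))), ncol = 2L,
                 byrow = TRUE)
    haplo[, j, ] <- 1L - al            # back to major-allele coding
    dosage[, j] <- as.integer(2L - rowSums(al))
  }
  f <- colMeans(dosage) / 2
  v$maf <- pmin(f, 1 - f)
  structure(list(dosage = dosage, variants = v,
                 window_index = rep(NA_integer_, s),
                 haplotypes = if (phased) haplo else NULL,
                 hap_ancestry = NULL),
            class = "genotype_panel")
}

#' Write local ancestry as an MSP-style TSV
#'
#' One row per window: chromosome, window start/end (bp and cM), then two
#' ancestry-code columns (0=EUR, 1=AFR, 2=AMR) per subject, one per
#' haplotype. Requires per-haplotype window ancestry, which is recovered
#' from the diploid dosages (the unordered pair determines the two codes).
#'
#' @param ancestry a `local_ancestry_panel`.
#' @param panel matching `genotype_panel` (for bp bounds); optional.
#' @param path output file.
#' @export
write_msp <- function(ancestry, path, panel = NULL) {
  dos <- ancestry$dosage_by_window
  n <- dim(dos)[1]; w <- dim(dos)[2]
  codes <- matrix("", w, 2L * n)
  for (i in seq_len(n)) {
    for (wi in seq_len(w)) {
      d <- dos[i, wi, ]
      pair <- rep(0:2, d)
      codes[wi, 2L * i - 1L] <- pair[1L]
      codes[wi, 2L * i] <- pair[2L]
    }
  }
  hdr <- c("chrom", "cm_start", "cm_end",
           as.vector(rbind(sprintf("S%04d.0", seq_len(n)),
                           sprintf("S%04d.1", seq_len(n)))))
  df <- cbind(ancestry$windows[, c("chrom", "cm_start", "cm_end")],
              as.data.frame(codes))
  names(df) <- hdr
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a template mesh as Wavefront OBJ
#'
#' @param template a [vault_template].
#' @param path output file.
#' @export
write_obj <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", template$vertices[, 1],
                     template$vertices[, 2], template$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", template$faces[, 1],
                     template$faces[, 2], template$faces[, 3]), con)
  invisible(path)
}

#' Read vertices and faces from an OBJ file
#'
#' @param path OBJ file.
#' @return list with `vertices` and `faces` (no mirror map).
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  colnames(vertices) <- c("x", "y", "z")
  list(vertices = vertices, faces = faces)
}

#' Write a cohort's coordinates as a packed TSV table
#'
#' Header line `n_subjects n_vertices`, then one row per subject with the
#' 3m coordinates in vertex-major x,y,z order.
#'
#' @param cohort a [mesh_cohort].
#' @param path output file.
#' @export
write_coords <- function(cohort, path) {
  X <- flatten_coords(cohort$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d", nrow(X), ncol(X) / 3L), con)
  utils::write.table(X, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a packed coordinate table
#'
#' @param path file written by [write_coords()].
#' @param template optional template to build a full [mesh_cohort].
#' @return n x m x 3 array, or a `mesh_cohort` when a template is given.
#' @export
read_coords <- function(path, template = NULL) {
  hdr <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  X <- as.matrix(read.table(path, skip = 1L, sep = "\t"))
  stopifnot(nrow(X) == hdr[1L], ncol(X) == 3L * hdr[2L])
  coords <- unflatten_coords(unname(X), hdr[2L])
  if (is.null(template)) coords else mesh_cohort(coords, template)
}

#' Write a segment hierarchy as JSON
#'
#' Vertex index lists are written 0-based; levels and content labels are
#' included.
#'
#' @param hierarchy a `segment_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy <- function(hierarchy, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write hierarchies")
  obj <- list(
    n_levels = hierarchy$n_levels,
    segments = lapply(seq_along(hierarchy$segments), function(i) list(
      id = i, level = hierarchy$level[i],
      content_label = hierarchy$content_label[i],
      vertices = hierarchy$segments[[i]] - 1L)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write GWAS summary statistics as a (gzipped) TSV
#'
#' One row per tested SNP: variant metadata, per-segment (r, chi2, df, p),
#' and the minimum p with its best segment.
#'
#' @param gwas a `gwas_result` from [run_gwas()].
#' @param panel the `genotype_panel` that was scanned.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_summary <- function(gwas, panel, path) {
  by <- gwas$by_snp
  v <- panel$variants[match(by$snp_id, panel$variants$id), ]
  wide <- data.frame(chrom = v$chrom, pos = v$bp, id = v$id,
                     major = v$allele_major, minor = v$allele_minor,
                     maf = v$maf)
  for (sid in unique(gwas$records$segment_id)) {
    rows <- gwas$records[gwas$records$segment_id == sid, ]
    rows <- rows[match(by$snp_id, rows$snp_id), ]
    wide[[paste0("r_seg", sid)]] <- rows$r
    wide[[paste0("chi2_seg", sid)]] <- rows$chi2
    wide[[paste0("df_seg", sid)]] <- rows$df
    wide[[paste0("p_seg", sid)]] <- rows$p
  }
  wide$min_p <- by$min_p
  wide$best_segment <- by$best_segment
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hotspot map as TSV and grayscale vertex-colored OBJ
#'
#' @param map per-vertex hotspot values (from [hotspots()]).
#' @param template the template mesh.
#' @param tsv_path,obj_path output files (either may be `NULL`).
#' @export
write_hotspots <- function(map, template, tsv_path = NULL, obj_path = NULL) {
  if (!is.null(tsv_path))
    write.table(data.frame(vertex = seq_along(map), hotspot = map),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(obj_path)) {
    g <- (map - min(map)) / max(max(map) - min(map), 1e-300)
    con <- file(obj_path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.6f %.6f %.6f %.4f %.4f %.4f",
                       template$vertices[, 1], template$vertices[, 2],
                       template$vertices[, 3], g, g, g), con)
    writeLines(sprintf("f %d %d %d", template$faces[, 1],
                       template$faces[, 2], template$faces[, 3]), con)
  }
  invisible(tsv_path)
}

#' Write clumped loci as BED plus a detail table
#'
#' BED uses 0-based half-open lead positions; the companion TSV lists lead
#' p-values and member SNPs.
#'
#' @param loci list of loci from [clump()].
#' @param bed_path,detail_path output files.
#' @export
write_loci <- function(loci, bed_path, detail_path) {
  bed <- data.frame(
    chrom = vapply(loci, `[[`, numeric(1L), "chrom"),
    start = vapply(loci, `[[`, numeric(1L), "bp") - 1,
    end = vapply(loci, `[[`, numeric(1L), "bp"),
    name = vapply(loci, `[[`, character(1L), "lead_snp"))
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  det <- data.frame(
    lead_snp = bed$name, chrom = bed$chrom, bp = bed$end,
    best_p = vapply(loci, `[[`, numeric(1L), "best_p"),
    n_members = vapply(loci, function(l) length(l$members), integer(1L)),
    members = vapply(loci, function(l) paste(l$members, collapse = ","),
                     character(1L)))
  write.table(det, detail_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
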