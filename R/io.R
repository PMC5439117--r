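#' Read a GISTIC-style gene x sample score matrix
#'
#' Tab-delimited, first column gene symbols, header row of sample IDs.
#' Duplicate genes or samples and non-numeric cells are errors; row and
#' column order are preserved.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_gistic_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_gistic_matrix: no genes in ", path)
  if (ncol(df) < 2L) stop("read_gistic_matrix: no sample columns in ", path)
  genes <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g)) {
    stop("read_gistic_matrix: duplicate gene symbol '", dup_g[1L], "'")
  }
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s)) {
    stop("read_gistic_matrix: duplicate sample ID '", dup_s[1L], "'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow = nrow(m)))) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" at row %d, column '%s'", bad[1, 1],
                                  samples[bad[1, 2]]) else ""
    stop("read_gistic_matrix: non-numeric score", loc)
  }
  if (any(!is.finite(m))) stop("read_gistic_matrix: non-finite score")
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a GISTIC-style matrix
#' @param m numeric gene x sample matrix.
#' @param path output path.
#' @export
write_gistic_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-style segment table
#'
#' TSV with columns sample(_id), chrom(osome), start, end, log2 (seg.mean
#' accepted). Chromosome names are normalized ("chr19" -> "19"); start must
#' not exceed end.
#'
#' @param path file path.
#' @return data.frame: sample_id, chrom, start, end, log2.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  syn <- list(sample_id = c("sample_id", "sample", "ID"),
              chrom = c("chrom", "chromosome", "chr"),
              start = c("start", "loc.start"),
              end = c("end", "loc.end"),
              log2 = c("log2", "seg.mean", "log2ratio", "value"))
  out <- list()
  for (col in names(syn)) {
    hit <- intersect(syn[[col]], tolower(names(df)))
    hit2 <- which(tolower(names(df)) %in% syn[[col]])
    if (!length(hit2)) {
      stop("read_segments: missing column '", col, "' (accepted: ",
           paste(syn[[col]], collapse = ", "), ")")
    }
    out[[col]] <- df[[hit2[1L]]]
  }
  out <- as.data.frame(out)
  out$chrom <- normalize_chrom(out$chrom)
  ok_chrom <- out$chrom %in% c(as.character(1:22), "X", "Y")
  if (any(!ok_chrom)) {
    stop("read_segments: unknown chromosome '", out$chrom[!ok_chrom][1L],
         "' at line ", which(!ok_chrom)[1L])
  }
  bad <- which(out$start > out$end)
  if (length(bad)) {
    stop("read_segments: start > end at line ", bad[1L])
  }
  out$log2 <- as.numeric(out$log2)
  if (anyNA(out$log2)) stop("read_segments: non-numeric log2 value")
  out
}

#' Read a MAF-like mutation table
#'
#' Minimum columns: sample (synonyms sample_id, Tumor_Sample_Barcode) and
#' gene (gene_symbol, Hugo_Symbol); variant_class(ification) optional.
#'
#' @param path file path.
#' @return data.frame: sample_id, gene, variant_class.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  pick <- function(syn, required = TRUE) {
    i <- which(lc %in% tolower(syn))
    if (!length(i)) {
      if (required) stop("read_mutations: missing column (expected one of: ",
                         paste(syn, collapse = ", "), ")")
      return(NULL)
    }
    df[[i[1L]]]
  }
  sample_id <- pick(c("sample_id", "sample", "Tumor_Sample_Barcode"))
  gene <- pick(c("gene", "gene_symbol", "Hugo_Symbol"))
  vc <- pick(c("variant_class", "Variant_Classification"), required = FALSE)
  if (is.null(vc)) vc <- rep("unknown", length(gene))
  if (any(!nzchar(gene))) stop("read_mutations: empty gene symbol")
  data.frame(sample_id = as.character(sample_id),
             gene = as.character(gene),
             variant_class = as.character(vc))
}

histology_codes <- c("A", "O", "OA", "AA", "AO", "AOA", "GBM", "unknown")

map_histology <- function(x) {
  x <- trimws(as.character(x))
  lut <- c(a = "A", astrocytoma = "A", "diffuse astrocytoma" = "A",
           o = "O", oligodendroglioma = "O",
           oa = "OA", oligoastrocytoma = "OA",
           aa = "AA", "anaplastic astrocytoma" = "AA",
           ao = "AO", "anaplastic oligodendroglioma" = "AO",
           aoa = "AOA", "anaplastic oligoastrocytoma" = "AOA",
           gbm = "GBM", glioblastoma = "GBM",
           "glioblastoma multiforme" = "GBM")
  out <- ifelse(x %in% histology_codes, x,
                unname(lut[tolower(x)]))
  out[is.na(out) | !nzchar(x)] <- "unknown"
  out
}

#' Read a clinical table
#'
#' Columns: sample_id, age_years, histology_2007, who_grade, kps,
#' os_months, event. Unknown histology or grade values map to "unknown",
#' never dropped. Missing fields may be empty strings. Negative survival or
#' age and non-binary event indicators are validation errors.
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "age_years", "histology_2007", "who_grade",
            "kps", "os_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_clinical: missing column(s): ", paste(miss, collapse = ", "),
         " (expected header: ", paste(need, collapse = "\t"), ")")
  }
  df$age_years <- as.numeric(df$age_years)
  df$os_months <- as.numeric(df$os_months)
  df$kps <- suppressWarnings(as.integer(df$kps))
  df$event <- suppressWarnings(as.integer(df$event))
  if (any(df$age_years < 0, na.rm = TRUE)) {
    stop("read_clinical: negative age")
  }
  if (any(df$os_months < 0, na.rm = TRUE)) {
    stop("read_clinical: negative os_months")
  }
  if (any(!df$event %in% c(0L, 1L) & !is.na(df$event))) {
    stop("read_clinical: event must be 0/1")
  }
  df$histology_2007 <- map_histology(df$histology_2007)
  gr <- trimws(as.character(df$who_grade))
  gr[is.na(gr) | !gr %in% c("II", "III", "IV")] <- "unknown"
  df$who_grade <- gr
  df[, need]
}

#' Write pipeline result tables plus a run manifest
#'
#' Each table is written as a TSV with fixed column order; tables with a
#' `sample_id` column are sorted by it, so reruns with the same seed and
#' config are byte-identical. A `manifest.json` records config, seed and
#' package version. Empty tables produce header-only files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration object to record.
#' @param seed optional seed to record.
#' @return (invisibly) the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("write_results: cannot create ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- as.data.frame(tables[[nm]])
    if ("sample_id" %in% names(tb) && nrow(tb)) {
      tb <- tb[order(tb$sample_id), , drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    paths <- c(paths, p)
  }
  if (!is.null(config)) config <- unclass(config)
  manifest <- list(
    package = "gcnaclass",
    version = as.character(utils::packageVersion("gcnaclass")),
    seed = seed,
    config = config,
    tables = names(tables))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}

#' Write a cohort's four input tables (+ truth) to a directory
#' @param cohort a `glioma_cohort`.
#' @param out_dir output directory.
#' @return (invisibly) the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gp <- file.path(out_dir, "gistic.tsv")
  write_gistic_matrix(cohort$gistic, gp)
  p <- write_results(list(segments = cohort$segments,
                          mutations = cohort$mutations,
                          clinical = cohort$clinical,
                          truth = cohort$truth),
                     out_dir, config = cohort$config,
                     seed = cohort$config$seed)
  invisible(c(gp, p))
}
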