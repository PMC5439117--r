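#' Default genomic regions (GRCh37)
#'
#' Returns the region map used for copy-number calling: the chromosome arms
#' 1p, 9p and 19q, the whole chromosomes 1, 4, 7, 10, 14, 19 and 20, and the
#' focal genes CDK4, MDM2, CDKN2A and EGFR. Coordinates are GRCh37/hg19,
#' 1-based inclusive; arm boundaries are cytoband-derived (p-arm ends at the
#' start of the pericentromeric band).
#'
#' @return A data.frame with columns `region`, `type` (one of `"arm"`,
#'   `"chrom"`, `"gene"`), `chrom`, `start`, `end`.
#' @export
default_regions <- function() {
  len <- grch37_chrom_lengths()
  rbind(
    data.frame(region = "1p",  type = "arm", chrom = "1",
               start = 1, end = 121535434),
    data.frame(region = "9p",  type = "arm", chrom = "9",
               start = 1, end = 47367679),
    data.frame(region = "19q", type = "arm", chrom = "19",
               start = 27681783, end = len[["19"]]),
    data.frame(region = c("chr1", "chr4", "chr7", "chr10",
                          "chr14", "chr19", "chr20"),
               type = "chrom",
               chrom = c("1", "4", "7", "10", "14", "19", "20"),
               start = 1,
               end = unname(len[c("1", "4", "7", "10", "14", "19", "20")])),
    data.frame(region = c("CDK4", "MDM2", "CDKN2A", "EGFR"),
               type = "gene",
               chrom = c("12", "12", "9", "7"),
               start = c(58141510, 69201956, 21967751, 55086714),
               end   = c(58149796, 69239214, 21995300, 55324313))
  )
}

#' GRCh37 chromosome lengths
#'
#' @return Named numeric vector of chromosome lengths (bp) for 1-22, X, Y.
#' @export
grch37_chrom_lengths <- function() {
  c("1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
    "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
    "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
    "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
    "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
    "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)
}

#' Default gene panel used by the synthetic generator and the GISTIC-route
#' region medians
#'
#' A compact panel of marker loci: evenly spaced pseudo-genes tiling each
#' arm/chromosome of interest (named e.g. \code{C7_G3}) plus the real focal
#' genes CDK4, MDM2, CDKN2A and EGFR at their GRCh37 coordinates. Pseudo-gene
#' coordinates are synthetic placeholders, not real loci.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
default_gene_annotation <- function() {
  len <- grch37_chrom_lengths()
  tile <- function(prefix, chrom, lo, hi, n) {
    pos <- round(seq(lo, hi, length.out = n + 2L))[2:(n + 1L)]
    data.frame(gene = sprintf("%s_G%d", prefix, seq_len(n)),
               chrom = chrom, start = pos, end = pos + 1e5)
  }
  rbind(
    tile("C1P", "1", 1, 121535434, 6),
    tile("C1Q", "1", 124535435, len[["1"]], 6),
    tile("C4",  "4", 1, len[["4"]], 6),
    tile("C7",  "7", 1, len[["7"]], 6),
    tile("C9P", "9", 1, 21000000, 3),     # 9p, clear of CDKN2A
    tile("C9P2", "9", 22500000, 47367679, 3),
    tile("C10", "10", 1, len[["10"]], 6),
    tile("C14", "14", 19100000, len[["14"]], 6),
    tile("C19P", "19", 1, 24681782, 4),
    tile("C19Q", "19", 27681783, len[["19"]], 6),
    tile("C20", "20", 1, len[["20"]], 6),
    data.frame(gene = c("CDK4", "MDM2", "CDKN2A", "EGFR"),
               chrom = c("12", "12", "9", "7"),
               start = c(58141510, 69201956, 21967751, 55086714),
               end   = c(58149796, 69239214, 21995300, 55324313))
  )
}

#' Map panel genes to regions by position
#'
#' A gene belongs to every region whose interval contains the gene midpoint
#' on the same chromosome.
#'
#' @param regions region table as from [default_regions()].
#' @param genes gene annotation as from [default_gene_annotation()].
#' @return Named list: region name -> character vector of member genes.
#' @export
region_gene_map <- function(regions = default_regions(),
                            genes = default_gene_annotation()) {
  mid <- (genes$start + genes$end) / 2
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    genes$gene[genes$chrom == r$chrom & mid >= r$start & mid <= r$end]
  })
  names(out) <- regions$region
  out
}

#' Default calling thresholds (log2 scale)
#'
#' Broad gains/losses are called at +/-0.5 on GISTIC scores and at +/-0.1 on
#' baseline-corrected segment medians; focal amplification and homozygous
#' deletion at +/-0.6. All comparisons are inclusive.
#'
#' @return list with elements `gistic_gain`, `gistic_loss`, `seg_gain`,
#'   `seg_loss`, `amp`, `homodel`.
#' @export
default_thresholds <- function() {
  thr <- list(gistic_gain = 0.5, gistic_loss = -0.5,
              seg_gain = 0.1, seg_loss = -0.1,
              amp = 0.6, homodel = -0.6)
  validate_thresholds(thr)
  thr
}

validate_thresholds <- function(thr) {
  stopifnot(thr$gistic_gain > 0, thr$seg_gain > 0,
            thr$gistic_loss < 0, thr$seg_loss < 0,
            thr$amp > thr$gistic_gain, thr$homodel < thr$gistic_loss)
  invisible(thr)
}

normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

is_autosome <- function(chrom) normalize_chrom(chrom) %in% as.character(1:22)
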