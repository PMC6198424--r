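# Interval bookkeeping shared by both scan arms: merging significant
# windows into regions, padding, sizing, annotation overlap and the
# genome-wide scan plot.

#' Merge significant windows into selection regions
#'
#' Windows on the same chromosome that share a SNP index or are directly
#' adjacent in SNP index are merged; the region spans the first SNP
#' position of the first window to the last SNP position of the last
#' window, and the region score is the maximum window value.
#'
#' @param windows Data frame as produced by [call_candidate_windows()]
#'   (`chrom`, `first`, `last`, `start`, `end`, `value`).
#' @return Data frame of regions: `chrom`, `start`, `end`, `size`
#'   (= end - start), `score`, `n_windows`.
#' @export
merge_windows <- function(windows) {
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), size = integer(), score = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  w <- windows[order(windows$chrom, windows$first), , drop = FALSE]
  out <- list()
  cur <- w[1, ]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$first[i] <= cur$last + 1L) {
      cur$last <- max(cur$last, w$last[i])
      cur$end <- max(cur$end, w$end[i])
      cur$value <- max(cur$value, w$value[i])
      cur$n_windows <- cur$n_windows + 1L
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- w[i, ]
      cur$n_windows <- 1L
    }
  }
  out[[length(out) + 1L]] <- cur
  m <- do.call(rbind, out)
  data.frame(chrom = m$chrom, start = m$start, end = m$end,
             size = m$end - m$start, score = m$value,
             n_windows = m$n_windows, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pad a region, clamped to the chromosome
#'
#' @param start,end 1-based inclusive bounds (vectors allowed).
#' @param pad Extension in bp on each side (`>= 0`).
#' @param chrom_length Chromosome length(s) for the ceiling (default
#'   `Inf`, i.e. unclamped).
#' @return List with padded `start` and `end`.
#' @export
pad_region <- function(start, end, pad, chrom_length = Inf) {
  if (any(pad < 0)) stop("pad must be >= 0")
  list(start = pmax(1, start - pad), end = pmin(chrom_length, end + pad))
}

#' Region size in bp
#'
#' Defined as `end - start`, the convention used throughout the scan
#' reports (a degenerate single-point region has size 0).
#'
#' @param start,end 1-based inclusive bounds.
#' @return `end - start`.
#' @export
region_size <- function(start, end) end - start

#' Overlap padded regions with an annotation file
#'
#' Features intersecting a padded region by at least 1 bp are reported.
#' BED input (0-based half-open) is converted to the internal 1-based
#' inclusive convention by the importer.
#'
#' @param regions Data frame with `chrom`, and either `pad_start` /
#'   `pad_end` or `start` / `end` (1-based inclusive).
#' @param annotation Path to a BED or GFF3 file, or a
#'   [GenomicRanges::GRanges] object.
#' @return Data frame with one row per (region, feature) intersection:
#'   region coordinates plus `feature_id`, `feature_start`,
#'   `feature_end`.
#' @export
overlap_genes <- function(regions, annotation) {
  gr_feat <- if (inherits(annotation, "GRanges")) annotation else
    rtracklayer::import(annotation)
  start <- if (!is.null(regions$pad_start)) regions$pad_start else regions$start
  end <- if (!is.null(regions$pad_end)) regions$pad_end else regions$end
  if (nrow(regions) == 0 || length(gr_feat) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), feature_id = character(),
                      feature_start = integer(), feature_end = integer(),
                      stringsAsFactors = FALSE))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_feat, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ids <- if (!is.null(gr_feat$Name)) gr_feat$Name else
    if (!is.null(gr_feat$name)) gr_feat$name else
      if (!is.null(gr_feat$ID)) gr_feat$ID else
        as.character(seq_along(gr_feat))
  data.frame(chrom = regions$chrom[qi], start = start[qi], end = end[qi],
             feature_id = as.character(ids)[si],
             feature_start = GenomicRanges::start(gr_feat)[si],
             feature_end = GenomicRanges::end(gr_feat)[si],
             stringsAsFactors = FALSE)
}

#' Genome-wide scan plot with an empirical threshold line
#'
#' Scatter of per-position values in genome order with per-chromosome
#' banding and a horizontal line at the empirical `percentile` of the
#' plotted values; the plotted table is also written as a TSV twin next
#' to the image.
#'
#' @param values Data frame with `chrom`, `pos` and `value`.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`); the TSV twin replaces the extension with
#'   `.tsv`.
#' @param percentile Threshold percentile of the plotted values
#'   (default 99.9); `NULL` suppresses the line.
#' @return List with `threshold` and the two output paths, invisibly.
#' @export
render_scan_plot <- function(values, path, percentile = 99.9) {
  tsv <- sub("\\.[^.]+$", ".tsv", path)
  utils::write.table(values, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  thr <- if (!is.null(percentile) && nrow(values) > 0)
    as.numeric(stats::quantile(values$value, percentile / 100,
                               type = 1, na.rm = TRUE)) else NA_real_
  if (nrow(values) > 0) {
    chroms <- unique(values$chrom)
    offs <- c(0, cumsum(vapply(chroms, function(ch)
      max(values$pos[values$chrom == ch]), numeric(1))))
    names(offs) <- c(chroms, "end")
    values$gpos <- values$pos + offs[match(values$chrom, chroms)]
    p <- ggplot2::ggplot(values,
                         ggplot2::aes(x = .data$gpos, y = .data$value,
                                      colour = .data$chrom)) +
      ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
      ggplot2::labs(x = "genome position (bp)", y = "value") +
      ggplot2::theme_minimal()
    if (!is.na(thr))
      p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  } else {
    p <- ggplot2::ggplot() + ggplot2::theme_void()
  }
  ggplot2::ggsave(path, p, width = 9, height = 3, dpi = 120)
  invisible(list(threshold = thr, plot = path, table = tsv))
}
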