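# VCF 4.2 emission (total and score-filtered callsets) and the run report
# (static HTML with read-length histogram, SV class donut, score-vs-ratio
# scatter, and a per-SV table; companion CSV).
#
# Internal coordinates are 0-based half-open and are converted to 1-based
# only here. DEL/INS/DUP/INV use symbolic ALT alleles; translocations and
# transpositions use BND bracket notation, distinguished by the SV2 INFO
# key.

#' Write calls as a VCF 4.2 file
#'
#' The header declares all INFO keys and the reference contigs; records are
#' sorted by chromosome and position. QUAL carries the confidence score S.
#' INFO keys: SVTYPE, END, SVLEN (negative for deletions), SV2 (partner
#' locus and BND subtype: translocation vs transposition), SR (supporting
#' reads B), BR (breakend read ratio), ZYG (zygosity estimate).
#'
#' @param calls scored call table (see [sv_call()])
#' @param path output VCF path
#' @param contig_lengths named vector of contig lengths for the header
#' @param reference optional `DNAStringSet`; when supplied, REF is the base
#'   at POS, otherwise `"N"`
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL, reference = NULL) {
  calls <- data.table::as.data.table(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=splitsv",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion of novel sequence\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the SV on the reference\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length; negative for deletions\">",
    "##INFO=<ID=SV2,Number=1,Type=String,Description=\"Partner locus and BND subtype (translocation/transposition)\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Breakend-supporting reads B\">",
    "##INFO=<ID=BR,Number=1,Type=Float,Description=\"Breakend read ratio B/(B+O)\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity estimate from the breakend read ratio\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ref_base <- function(chrom, pos1based) {
    if (is.null(reference)) return(rep("N", length(pos1based)))
    vapply(seq_along(chrom), function(i) {
      sq <- reference[[chrom[i]]]
      p <- min(max(pos1based[i], 1L), length(sq))
      as.character(Biostrings::subseq(sq, p, p))
    }, character(1))
  }
  pos <- calls$pos1 + 1L                                 # 1-based
  is_bnd <- calls$sv_class == "BND"
  alt <- character(nrow(calls))
  alt[!is_bnd] <- paste0("<", calls$sv_class[!is_bnd], ">")
  refs <- ref_base(calls$chrom1, pos)
  # bracket notation: t[chr:pos[ places the partner after the breakend base
  if (any(is_bnd)) {
    partner <- ifelse(!is.na(calls$pos2[is_bnd]),
                      paste0(calls$chrom2[is_bnd], ":", calls$pos2[is_bnd] + 1L),
                      paste0(calls$chrom1[is_bnd], ":", pos[is_bnd]))
    alt[is_bnd] <- paste0(refs[is_bnd], "[", partner, "[")
  }
  svlen <- data.table::fcase(
    calls$sv_class == "DEL", -abs(calls$sv_size),
    calls$sv_class %in% c("INS", "DUP", "INV", "BND"), abs(calls$sv_size),
    default = NA_integer_)
  info <- paste0(
    "SVTYPE=", calls$sv_class,
    ifelse(!is_bnd & !is.na(calls$pos2), paste0(";END=", calls$pos2 + 1L), ""),
    ifelse(is.na(svlen), "", paste0(";SVLEN=", svlen)),
    ifelse(is_bnd,
           paste0(";SV2=", ifelse(is.na(calls$bnd_subtype), "breakend",
                                  calls$bnd_subtype),
                  ifelse(is.na(calls$pos2), "",
                         paste0("_", calls$chrom2, ":", calls$pos2 + 1L))),
           ""),
    ";SR=", calls$B,
    ";BR=", formatC(calls$ratio, digits = 4, format = "f"),
    ";ZYG=", calls$zygosity %||% "UNKNOWN")
  rec <- data.table::data.table(
    CHROM = calls$chrom1, POS = pos, ID = calls$id, REF = refs, ALT = alt,
    QUAL = formatC(calls$score, digits = 3, format = "f"), FILTER = "PASS",
    INFO = info)
  data.table::setorder(rec, CHROM, POS)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the run report (static HTML + CSV)
#'
#' The HTML report contains the read-length histogram of the input reads,
#' a donut chart of SV class proportions, a scatter plot of confidence
#' score against breakend read ratio with the score threshold marked, and a
#' per-SV table. The companion CSV holds one row per SV in the filtered
#' callset.
#'
#' @param callset an `sv_callset` from [sv_call()]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix (default `"splitsv"`)
#' @return named character vector of the files written, invisibly
#' @export
write_report <- function(callset, dir, prefix = "splitsv") {
  stopifnot(inherits(callset, "sv_callset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  filtered <- filter_by_score(callset$calls, callset$params$score_threshold)
  csv <- file.path(dir, paste0(prefix, "_sv_table.csv"))
  cols <- intersect(c("id", "sv_class", "bnd_subtype", "chrom1", "pos1",
                      "chrom2", "pos2", "sv_size", "B", "O", "ratio",
                      "score", "zygosity"), names(filtered))
  utils::write.csv(filtered[, cols, with = FALSE], csv, row.names = FALSE)

  figures <- character(0)
  can_plot <- capabilities("png")
  if (can_plot && nrow(callset$calls) > 0L) {
    fig <- file.path(dir, paste0(prefix, "_figures.png"))
    grDevices::png(fig, width = 1400, height = 480, res = 96)
    graphics::par(mfrow = c(1, 3), mar = c(4.5, 4.5, 3, 1))
    plot_read_lengths(callset)
    plot_class_donut(filtered)
    plot(callset)
    grDevices::dev.off()
    figures <- basename(fig)
  }

  html <- file.path(dir, paste0(prefix, "_report.html"))
  tab <- utils::read.csv(csv, check.names = FALSE)
  writeLines(c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>splitsv run report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:3px 8px;font-size:90%}</style></head><body>",
    "<h1>splitsv run report</h1>",
    sprintf("<p>Total SVs: %d; filtered (score &ge; %.2f): %d; depth median %.1f; U = %.2f</p>",
            nrow(callset$calls), callset$params$score_threshold,
            nrow(filtered), callset$depth$median,
            depth_outlier_threshold(callset$depth)),
    if (length(figures) > 0L)
      sprintf("<img src='%s' style='max-width:100%%'>", figures),
    "<h2>Filtered SV calls</h2>",
    html_table(tab),
    "</body></html>"), html)
  invisible(c(html = html, csv = csv,
              if (length(figures) > 0L) c(figures = file.path(dir, figures))))
}

html_table <- function(df) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  head <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                collapse = ""), "</tr>")
  if (nrow(df) == 0L) return(paste0("<table>", head, "</table>"))
  body <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head, paste(body, collapse = "\n"), "</table>")
}

plot_read_lengths <- function(callset) {
  rl <- callset$read_stats$read_length
  graphics::hist(rl / 1000, breaks = 40, col = "steelblue", border = NA,
                 main = "Read length QC", xlab = "read length (kb)")
}

plot_class_donut <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(invisible())
  tab <- calls[, .N, by = sv_class][order(sv_class)]
  graphics::pie(tab$N, labels = paste0(tab$sv_class, " (", tab$N, ")"),
                col = grDevices::hcl.colors(nrow(tab), "Set2"),
                main = "SV class distribution")
  graphics::symbols(0, 0, circles = 0.45, inches = FALSE, add = TRUE,
                    bg = "white", fg = "white")
}

#' Fractions of SV classes in a callset
#' @param calls call table
#' @return named numeric vector summing to 1 (empty input gives an empty
#'   vector)
#' @export
class_fractions <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(numeric(0))
  tab <- table(calls$sv_class)
  as.numeric(tab) / sum(tab) -> fr
  setNames(fr, names(tab))
}
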