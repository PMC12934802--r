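# Static miropeats-style ribbon rendering of identity stats rows as SVG.
#
# Layout: target axis on top, query axis on bottom; one ribbon per stats row
# connecting the target and query intervals, blue (#3b6fb6) for forward and
# orange (#e07b39) for reverse alignments; ribbon opacity encodes
# perID_by_matches via an affine map from [min displayed identity, 100] to
# [0.2, 1.0]; a grey percent-identity profile track sits below the target
# axis; optional BED annotation blocks are drawn alongside either axis.
# Output is plain deterministic text: identical input gives byte-identical
# SVG.

COL_FWD <- "#3b6fb6"
COL_REV <- "#e07b39"

svg_num <- function(x) fmt_fixed(x, 2L)

# map identity to ribbon opacity over the displayed range
identity_opacity <- function(id, min_id) {
  if (min_id >= 100) return(rep(1, length(id)))
  0.2 + 0.8 * (id - min_id) / (100 - min_id)
}

# itemRgb ("r,g,b") from a BED extra payload (columns 5+ verbatim), if any
anno_color <- function(extra) {
  f <- strsplit(extra, "\t", fixed = TRUE)[[1]]
  if (length(f) >= 5L && grepl("^[0-9]+,[0-9]+,[0-9]+$", f[5L])) {
    rgb <- as.integer(strsplit(f[5L], ",", fixed = TRUE)[[1]])
    return(sprintf("#%02x%02x%02x", rgb[1L], rgb[2L], rgb[3L]))
  }
  "#888888"
}

#' Render stats rows as a miropeats-style ribbon plot (SVG)
#'
#' @param rows a stats data frame ([paf_stats()] / [read_stats()]).
#' @param file output path for the SVG, or `NULL` to only return the text.
#' @param target_region optional one-row BED data frame (`chrom`, `start`,
#'   `end`); only rows of that target name overlapping the interval are
#'   displayed. An empty intersection is an error listing the available
#'   target names.
#' @param annotations list of annotation tracks, each a list with elements
#'   `label` (text), `intervals` (a BED data frame; itemRgb in BED9 `extra`
#'   honored) and `side` (`"target"` or `"query"`).
#' @param width,height canvas size in pixels.
#' @return The SVG document as a character vector of lines, invisibly.
#' @export
plot_ribbons <- function(rows, file = NULL, target_region = NULL,
                         annotations = list(), width = 900, height = 480) {
  if (!nrow(rows)) paf_error("plot_ribbons: no stats rows to draw")
  if (!is.null(target_region)) {
    sel <- rows$tname == target_region$chrom &
      rows$tstart < target_region$end & rows$tend > target_region$start
    if (!any(sel)) {
      paf_error("plot_ribbons: region matches no alignment; available targets: ",
                paste(sort(unique(rows$tname)), collapse = ", "))
    }
    rows <- rows[sel, , drop = FALSE]
    t_lo <- target_region$start
    t_hi <- target_region$end
  } else {
    t_lo <- min(rows$tstart)
    t_hi <- max(rows$tend)
  }

  margin <- 40
  y_t <- 110                       # target axis
  y_id0 <- y_t + 12                # identity track top
  id_h <- 36
  y_q <- height - 110              # query axis
  xspan <- width - 2 * margin

  xt <- function(p) margin + xspan * (p - t_lo) / max(1, t_hi - t_lo)

  # queries laid out consecutively along the bottom axis, in order of first
  # appearance, separated by a fixed 1% gap
  qn <- unique(rows$qname)
  q_lo <- vapply(qn, function(q) min(rows$qstart[rows$qname == q]), numeric(1))
  q_hi <- vapply(qn, function(q) max(rows$qend[rows$qname == q]), numeric(1))
  spans <- pmax(1, q_hi - q_lo)
  gapx <- 0.01 * xspan
  total <- sum(spans)
  scale_q <- (xspan - gapx * (length(qn) - 1)) / total
  q_off <- cumsum(c(0, utils::head(spans * scale_q + gapx, -1)))
  names(q_off) <- qn
  xq <- function(q, p) margin + q_off[[q]] + (p - q_lo[[q]]) * scale_q

  min_id <- min(rows$perID_by_matches)
  opac <- identity_opacity(rows$perID_by_matches, min_id)

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            as.integer(width), as.integer(height), as.integer(width), as.integer(height)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            as.integer(width), as.integer(height))
  )

  # ribbons (drawn first, axes on top)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    x1 <- xt(max(r$tstart, t_lo))
    x2 <- xt(min(r$tend, t_hi))
    qa <- xq(r$qname, r$qstart)
    qb <- xq(r$qname, r$qend)
    # reverse alignments twist: target start joins query end
    q_right <- if (r$strand == "+") qb else qa
    q_left <- if (r$strand == "+") qa else qb
    out <- c(out, sprintf(
      '<path class="ribbon" d="M %s %s L %s %s L %s %s L %s %s Z" fill="%s" fill-opacity="%s" stroke="none"/>',
      svg_num(x1), svg_num(y_id0 + id_h + 4), svg_num(x2), svg_num(y_id0 + id_h + 4),
      svg_num(q_right), svg_num(y_q), svg_num(q_left), svg_num(y_q),
      if (r$strand == "+") COL_FWD else COL_REV, svg_num(opac[i])
    ))
  }

  # percent-identity profile track below the target axis
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    frac <- if (min_id >= 100) 1 else (r$perID_by_matches - min_id) / (100 - min_id)
    h <- id_h * frac
    out <- c(out, sprintf(
      '<rect class="idtrack" x="%s" y="%s" width="%s" height="%s" fill="#777777" fill-opacity="0.8"/>',
      svg_num(xt(max(r$tstart, t_lo))), svg_num(y_id0 + id_h - h),
      svg_num(max(0.5, xt(min(r$tend, t_hi)) - xt(max(r$tstart, t_lo)))),
      svg_num(max(0.5, h))
    ))
  }

  # axes and labels
  out <- c(out,
    sprintf('<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="#222222" stroke-width="2"/>',
            svg_num(margin), y_t, svg_num(width - margin), y_t),
    sprintf('<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="#222222" stroke-width="2"/>',
            svg_num(margin), y_q, svg_num(width - margin), y_q),
    sprintf('<text x="%s" y="%d" font-family="sans-serif" font-size="12">%s:%d-%d</text>',
            svg_num(margin), y_t - 26, xml_escape(rows$tname[1]),
            as.integer(t_lo), as.integer(t_hi))
  )
  for (q in qn) {
    out <- c(out, sprintf(
      '<text x="%s" y="%d" font-family="sans-serif" font-size="12">%s</text>',
      svg_num(margin + q_off[[q]]), y_q + 24, xml_escape(q)))
  }

  # annotation tracks
  for (a in annotations) {
    side <- match.arg(a$side, c("target", "query"))
    iv <- a$intervals
    ylab <- if (side == "target") y_t - 20 else y_q + 40
    for (k in seq_len(nrow(iv))) {
      if (side == "target") {
        if (iv$chrom[k] != rows$tname[1]) next
        xa <- xt(max(iv$start[k], t_lo))
        xb <- xt(min(iv$end[k], t_hi))
        if (xb <= xa) next
      } else {
        if (!(iv$chrom[k] %in% qn)) next
        xa <- xq(iv$chrom[k], iv$start[k])
        xb <- xq(iv$chrom[k], iv$end[k])
      }
      out <- c(out, sprintf(
        '<rect class="anno" x="%s" y="%d" width="%s" height="8" fill="%s"/>',
        svg_num(xa), as.integer(ylab - 4), svg_num(max(0.5, xb - xa)),
        anno_color(iv$extra[k])
      ))
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%d" font-family="sans-serif" font-size="10">%s</text>',
      svg_num(width - margin + 4), as.integer(ylab + 4), xml_escape(a$label)))
  }

  out <- c(out, "</svg>")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
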