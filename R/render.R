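#' Rendering options
#'
#' @param format `"svg"`, `"png"`, or `"html"`.
#' @param width,height Canvas size in pixels.
#' @param hue HCL hue of the sector color ramp.
#' @param padding Angular padding as a fraction of the sector span, trimmed
#'   from each side when drawing; must lie in \[0, 0.2).
#' @param font_size Base font size in px.
#' @param title Optional chart title.
#' @return List of class `pl_render_options`.
#' @export
render_options <- function(format = c("svg", "png", "html"),
                           width = 800, height = 800, hue = 260,
                           padding = 0.02, font_size = 13, title = NULL) {
  format <- match.arg(format)
  if (!is.numeric(padding) || padding < 0 || padding >= 0.2)
    stop("'padding' must be in [0, 0.2)")
  structure(list(format = format, width = width, height = height,
                 hue = hue, padding = padding, font_size = font_size,
                 title = title),
            class = "pl_render_options")
}

# fixed-precision number formatting keeps SVG output byte-stable
fmt <- function(x) sprintf("%.6f", x)

# polar (degrees, counterclockwise, 0 = +x axis) -> SVG canvas coordinates
polar_xy <- function(angle_deg, r, cx, cy, scale) {
  th <- angle_deg * pi / 180
  c(cx + scale * r * cos(th), cy - scale * r * sin(th))
}

svg_wedge <- function(start, end, radius, cx, cy, scale, fill, extra = "") {
  if (end - start >= 360) {
    return(sprintf(
      '<circle class="sector" cx="%s" cy="%s" r="%s" fill="%s" stroke="#555" stroke-width="1"%s/>',
      fmt(cx), fmt(cy), fmt(scale * radius), fill, extra))
  }
  p0 <- polar_xy(start, radius, cx, cy, scale)
  p1 <- polar_xy(end, radius, cx, cy, scale)
  large <- if ((end - start) > 180) 1 else 0
  sprintf(
    '<path class="sector" d="M %s %s L %s %s A %s %s 0 %d 0 %s %s Z" fill="%s" stroke="#555" stroke-width="1"%s/>',
    fmt(cx), fmt(cy), fmt(p0[1]), fmt(p0[2]),
    fmt(scale * radius), fmt(scale * radius), large,
    fmt(p1[1]), fmt(p1[2]), fill, extra)
}

# shared SVG builder; tooltips add native <title> children (hover text)
layout_svg <- function(layout, options = render_options(),
                       tooltips = FALSE) {
  w <- options$width; h <- options$height
  cx <- w / 2; cy <- h / 2
  scale <- 0.42 * min(w, h)
  s <- layout$sectors
  if (is.null(s$color)) layout <- assign_styles(layout, hue = options$hue)
  s <- layout$sectors
  pts <- layout$points
  pad <- options$padding
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    round(w), round(h), round(w), round(h)),
    sprintf('<rect width="%d" height="%d" fill="white"/>',
            round(w), round(h)))
  if (!is.null(options$title))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" font-size="%s" font-family="sans-serif">%s</text>',
      fmt(cx), fmt(0.05 * h), fmt(options$font_size * 1.3),
      xml_escape(options$title)))

  # radial scale: reference circles at quarter fractions of the max feature
  maxfeat <- max(s$feature)
  for (fr in c(0.25, 0.5, 0.75, 1)) {
    out <- c(out, sprintf(
      '<circle class="grid" cx="%s" cy="%s" r="%s" fill="none" stroke="#cccccc" stroke-width="0.8" stroke-dasharray="4 3"/>',
      fmt(cx), fmt(cy), fmt(scale * fr)))
    out <- c(out, sprintf(
      '<text class="gridlab" x="%s" y="%s" font-size="%s" fill="#888888" font-family="sans-serif">%s</text>',
      fmt(cx + scale * fr + 3), fmt(cy - 3), fmt(options$font_size * 0.75),
      sprintf("%.3g", fr * maxfeat)))
  }

  for (i in seq_len(nrow(s))) {
    span <- s$end_deg[i] - s$start_deg[i]
    a0 <- s$start_deg[i] + pad * span
    a1 <- s$end_deg[i] - pad * span
    tt <- if (tooltips && isTRUE(layout$lasso_mode)) {
      j <- which(pts$group == s$group[i])[1]
      sprintf("<title>%s</title>", xml_escape(pts$tooltip[j]))
    } else ""
    wedge <- svg_wedge(a0, a1, s$radius[i], cx, cy, scale, s$color[i])
    if (nzchar(tt)) {
      tag <- if (grepl("^<circle", wedge)) "circle" else "path"
      wedge <- sub("/>$", sprintf(">%s</%s>", tt, tag), wedge)
    }
    out <- c(out, wedge)
    # sector label along the outer rim
    lab <- polar_xy((s$start_deg[i] + s$end_deg[i]) / 2,
                    s$radius[i] + 0.07, cx, cy, scale)
    out <- c(out, sprintf(
      '<text class="seclab" x="%s" y="%s" text-anchor="middle" font-size="%s" font-family="sans-serif">%s</text>',
      fmt(lab[1]), fmt(lab[2]), fmt(options$font_size * 0.85),
      xml_escape(s$group[i])))
  }

  sec_r <- s$radius[match(pts$group, s$group)]
  for (i in seq_len(nrow(pts))) {
    xy <- polar_xy(pts$angle_deg[i], pts$rel_radius[i] * sec_r[i],
                   cx, cy, scale)
    tt <- if (tooltips)
      sprintf("<title>%s</title>", xml_escape(pts$tooltip[i])) else ""
    if (pts$symbol[i] == "positive") {
      out <- c(out, sprintf(
        '<circle class="point point-positive" cx="%s" cy="%s" r="4" fill="#222222" stroke="white" stroke-width="0.8">%s</circle>',
        fmt(xy[1]), fmt(xy[2]), tt))
    } else {
      out <- c(out, sprintf(
        '<rect class="point point-negative" x="%s" y="%s" width="7" height="7" fill="#b2182b" stroke="white" stroke-width="0.8">%s</rect>',
        fmt(xy[1] - 3.5), fmt(xy[2] - 3.5), tt))
    }
  }

  # legend: color -> group size, symbol -> sign
  sizes <- sort(unique(s$size))
  show <- sizes[unique(round(seq(1, length(sizes),
                                 length.out = min(5, length(sizes)))))]
  rng <- range(s$size)
  lx <- 0.02 * w; ly <- 0.90 * h
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif">group size</text>',
    fmt(lx), fmt(ly - 10), fmt(options$font_size * 0.85)))
  for (i in seq_along(show)) {
    cv <- if (rng[1] == rng[2]) 0.5 else (show[i] - rng[1]) / (rng[2] - rng[1])
    out <- c(out, sprintf(
      '<rect class="legend" x="%s" y="%s" width="14" height="14" fill="%s" stroke="#555"/>',
      fmt(lx + (i - 1) * 48), fmt(ly), size_color(cv, options$hue)))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" font-family="sans-serif">%d</text>',
      fmt(lx + (i - 1) * 48 + 18), fmt(ly + 12),
      fmt(options$font_size * 0.8), show[i]))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="%s" font-family="sans-serif">&#9679; positive&#160;&#160;&#9632; negative coefficient</text>',
    fmt(lx), fmt(ly + 34), fmt(options$font_size * 0.8)))
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a chart layout to a static image
#'
#' Writes an SVG (deterministic, byte-stable for identical layout and
#' options) or a PNG. Every sector is drawn as a wedge at its layout angles
#' and radius, points use sign-dependent markers (filled circle positive,
#' filled square negative), dashed circles give the radial feature scale,
#' and a legend maps color to group size.
#'
#' @param layout A `pl_layout`.
#' @param path Output file; extension picks the format unless `options`
#'   overrides it.
#' @param options A [render_options()].
#' @return `path`, invisibly.
#' @export
render_static <- function(layout, path, options = render_options()) {
  ext <- tolower(tools::file_ext(path))
  format <- if (ext %in% c("svg", "png")) ext else options$format
  if (format == "png") return(render_png(layout, path, options))
  writeLines(layout_svg(layout, options, tooltips = FALSE), path,
             useBytes = TRUE)
  invisible(path)
}

render_png <- function(layout, path, options = render_options()) {
  grDevices::png(path, width = options$width, height = options$height,
                 res = 96)
  on.exit(grDevices::dev.off())
  draw_layout_base(layout, options)
  invisible(path)
}

#' Plot a chart layout on the current graphics device
#'
#' @param x A `pl_layout`.
#' @param ... Passed to [render_options()].
#' @export
plot.pl_layout <- function(x, ...) {
  draw_layout_base(x, render_options(...))
  invisible(x)
}

draw_layout_base <- function(layout, options) {
  if (is.null(layout$sectors$color))
    layout <- assign_styles(layout, hue = options$hue)
  s <- layout$sectors; pts <- layout$points
  graphics::plot.new()
  graphics::plot.window(c(-1.25, 1.25), c(-1.25, 1.25), asp = 1)
  for (fr in c(0.25, 0.5, 0.75, 1)) {
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(fr * cos(th), fr * sin(th), col = "grey80", lty = 3)
  }
  pad <- options$padding
  for (i in seq_len(nrow(s))) {
    span <- s$end_deg[i] - s$start_deg[i]
    th <- seq((s$start_deg[i] + pad * span) * pi / 180,
              (s$end_deg[i] - pad * span) * pi / 180, length.out = 60)
    graphics::polygon(c(0, s$radius[i] * cos(th)),
                      c(0, s$radius[i] * sin(th)),
                      col = s$color[i], border = "grey30")
    mid <- (s$start_deg[i] + s$end_deg[i]) / 2 * pi / 180
    graphics::text(1.12 * s$radius[i] * cos(mid),
                   1.12 * s$radius[i] * sin(mid), s$group[i], cex = 0.8)
  }
  sec_r <- s$radius[match(pts$group, s$group)]
  th <- pts$angle_deg * pi / 180
  r <- pts$rel_radius * sec_r
  pos <- pts$symbol == "positive"
  graphics::points(r[pos] * cos(th[pos]), r[pos] * sin(th[pos]),
                   pch = 19, col = "grey10")
  graphics::points(r[!pos] * cos(th[!pos]), r[!pos] * sin(th[!pos]),
                   pch = 15, col = "#b2182b")
  if (!is.null(options$title)) graphics::title(main = options$title)
}

#' Render a chart layout to interactive HTML
#'
#' Writes a single self-contained HTML file embedding the SVG chart.
#' Hovering an inner-level point shows its tooltip ("group / variable /
#' coefficient", coefficient to 4 decimals); in lasso mode the whole sector
#' is also a hover target carrying its variable's information.
#'
#' @inheritParams render_static
#' @return `path`, invisibly.
#' @export
render_interactive <- function(layout, path, options = render_options()) {
  svg <- layout_svg(layout, options, tooltips = TRUE)
  title <- if (is.null(options$title)) "Multi-level polar chart"
           else options$title
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", xml_escape(title), "</title>\n",
    "<style>body{font-family:sans-serif;margin:16px}",
    ".point:hover{stroke:#000;stroke-width:2px;cursor:pointer}",
    ".sector:hover{stroke:#000;stroke-width:2px}</style>\n",
    "</head>\n<body>\n", svg, "\n</body>\n</html>\n")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
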