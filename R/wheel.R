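# Profile-wheel rendering: the circular overview divided into 4 equal
# quadrants (one per domain) with up to 6 colored parameter icons each,
# plus per-parameter detail panels showing each element as a colored
# cutoff bar with the numeric score and a position marker. Output is
# standalone SVG 1.1 text, byte-identical for identical inputs.

#' Default wheel layout
#'
#' Quadrant order follows the config's domain order, starting at the
#' top-left and proceeding clockwise. Colors, radii and the per-quadrant
#' icon budget (6) are layout data; the spec of the original figures does
#' not fix them, so they are free choices exposed here.
#'
#' @param config a `diag360_config`.
#' @return A layout list used by [render_wheel()].
#' @export
default_wheel_layout <- function(config) {
  list(
    size = 600,
    outer_radius = 260,
    icon_radius = 0.66,   # icon centre as a fraction of outer radius
    icon_size = 22,
    start_angle = 270,    # degrees clockwise from 12 o'clock; 270 = top-left quadrant
    max_icons = 6,
    quadrant_order = config$domain_order,
    colors = list(green = "#2e8b57", orange = "#f28c28", red = "#d13b3b",
                  gray = "#9e9e9e"),
    quadrant_fills = c("#f6f6f6", "#ededed", "#f6f6f6", "#ededed"),
    decimal_mark = "."
  )
}

num <- function(x) formatC(x, format = "f", digits = 2, decimal.mark = ".")

polar_point <- function(cx, cy, r, angle_deg) {
  a <- angle_deg * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

svg_open <- function(width, height) {
  sprintf(paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
    "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
    width, height, width, height)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the profile wheel
#'
#' One colored icon per parameter, grouped into 4 equal 90-degree
#' quadrants in domain order. Icon fill encodes the parameter's
#' traffic-light status (gray when undetermined). Each icon group carries
#' a stable `id` (`icon-<parameter_id>`) and a `data-detail` attribute so
#' a report can link it to the parameter's detail panel. Rendering is
#' deterministic: identical profile + layout give byte-identical SVG.
#'
#' @param profile a `diag360_profile`.
#' @param config the `diag360_config` the profile was built with.
#' @param layout a layout list; defaults to [default_wheel_layout()].
#' @return SVG document as a single character string.
#' @export
render_wheel <- function(profile, config, layout = NULL) {
  stopifnot(inherits(profile, "diag360_profile"))
  if (!identical(profile$config_id, config$config_id)) {
    stop(sprintf("profile was built with config '%s', not '%s'",
                 profile$config_id, config$config_id))
  }
  if (!setequal(names(profile$parameter_status), config$parameter_order)) {
    stop("profile parameter set does not match the config")
  }
  if (is.null(layout)) layout <- default_wheel_layout(config)
  quadrants <- layout$quadrant_order
  if (length(quadrants) != 4L) stop("layout must declare exactly 4 quadrants")

  size <- layout$size
  cx <- size / 2; cy <- size / 2
  r_out <- layout$outer_radius
  r_icon <- layout$icon_radius * r_out

  out <- c(svg_open(size, size),
           sprintf("<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"#ffffff\" stroke=\"#cccccc\"/>",
                   num(cx), num(cy), num(r_out + 6)))

  for (q in seq_along(quadrants)) {
    dom_id <- quadrants[[q]]
    dom <- config$domains[[dom_id]]
    if (is.null(dom)) stop("layout quadrant references unknown domain: ", dom_id)
    pids <- unlist(dom$parameter_ids)
    if (length(pids) > layout$max_icons) {
      stop(sprintf("domain '%s' has %d parameters; at most %d icons fit in a quadrant",
                   dom_id, length(pids), layout$max_icons))
    }
    a0 <- (layout$start_angle + (q - 1L) * 90) %% 360
    a1 <- a0 + 90
    p0 <- polar_point(cx, cy, r_out, a0)
    p1 <- polar_point(cx, cy, r_out, a1)
    out <- c(out, sprintf("<g id=\"quadrant-%s\" class=\"quadrant\" data-span=\"90\">", dom_id))
    out <- c(out, sprintf(
      "<path d=\"M %s %s L %s %s A %s %s 0 0 1 %s %s Z\" fill=\"%s\" stroke=\"#ffffff\" stroke-width=\"2\"/>",
      num(cx), num(cy), num(p0[1]), num(p0[2]), num(r_out), num(r_out),
      num(p1[1]), num(p1[2]), layout$quadrant_fills[[q]]))
    lab <- polar_point(cx, cy, r_out * 0.9, a0 + 45)
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"13\" text-anchor=\"middle\" fill=\"#555555\">%s</text>",
      num(lab[1]), num(lab[2]), xml_escape(cfg_label(dom))))
    for (j in seq_along(pids)) {
      pid <- pids[[j]]
      par <- config$parameters[[pid]]
      status <- profile$parameter_status[[pid]]
      fill <- layout$colors[[status]]
      ang <- a0 + 90 * (j - 0.5) / length(pids)
      c_pt <- polar_point(cx, cy, r_icon, ang)
      glyph <- toupper(substr(par$icon_id %||% pid, 1L, 2L))
      out <- c(out, sprintf(
        "<g id=\"icon-%s\" class=\"param-icon\" data-status=\"%s\" data-detail=\"detail-%s.svg\">",
        pid, status, pid))
      out <- c(out, sprintf("<title>%s</title>", xml_escape(cfg_label(par))))
      out <- c(out, sprintf(
        "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
        num(c_pt[1]), num(c_pt[2]), num(layout$icon_size), fill))
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"12\" text-anchor=\"middle\" fill=\"#ffffff\">%s</text>",
        num(c_pt[1]), num(c_pt[2] + 4), xml_escape(glyph)))
      out <- c(out, "</g>")
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Render a per-parameter detail panel
#'
#' One horizontal band bar per element of the parameter: colored segments
#' at the cutoff positions over the element's valid range, the patient's
#' score as a black number, and a small black triangle marking its
#' position on the bar. An element whose input was absent renders its bar
#' with an explicit "not answered" annotation and no marker.
#'
#' @param profile a `diag360_profile`.
#' @param parameter_id a parameter declared in `config`.
#' @param config the matching `diag360_config`.
#' @param layout optional layout list (colors, decimal mark).
#' @return SVG document as a single character string.
#' @export
render_detail <- function(profile, parameter_id, config, layout = NULL) {
  stopifnot(inherits(profile, "diag360_profile"))
  par <- cfg_parameter(config, parameter_id)
  if (is.null(layout)) layout <- default_wheel_layout(config)
  eids <- unlist(par$element_ids)

  width <- 520
  bar_x <- 70; bar_w <- 400; bar_h <- 22
  row_h <- 80
  height <- 50 + row_h * length(eids)

  out <- c(svg_open(width, height))
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"28\" font-size=\"17\" fill=\"#111111\">%s</text>",
    num(bar_x), xml_escape(cfg_label(par))))

  for (k in seq_along(eids)) {
    eid <- eids[[k]]
    e <- config$elements[[eid]]
    y <- 50 + row_h * (k - 1L) + 20
    out <- c(out, sprintf("<g id=\"element-%s\" class=\"element-bar\">", eid))
    lab <- cfg_label(e)
    if (is_scalar_string(e$units) && nzchar(e$units)) {
      lab <- paste0(lab, " (", e$units, ")")
    }
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-size=\"12\" fill=\"#333333\">%s</text>",
      num(bar_x), num(y - 6), xml_escape(lab)))

    categorical <- identical(e$value_kind, "categorical")
    if (categorical) {
      cats <- unlist(e$categories)
      seg_w <- bar_w / length(cats)
      for (ci in seq_along(cats)) {
        st <- classify_element(eid, cats[[ci]], config)
        out <- c(out, sprintf(
          "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" class=\"band-%s\"/>",
          num(bar_x + (ci - 1L) * seg_w), num(y + 14), num(seg_w), num(bar_h),
          layout$colors[[st]], st))
      }
    } else {
      lo <- e$range[[1L]]; hi <- e$range[[2L]]
      bands <- e$bands[order(vapply(e$bands, function(b) b$lower, 0))]
      for (b in bands) {
        x0 <- bar_x + bar_w * (b$lower - lo) / (hi - lo)
        x1 <- bar_x + bar_w * (b$upper - lo) / (hi - lo)
        out <- c(out, sprintf(
          "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" class=\"band-%s\"/>",
          num(x0), num(y + 14), num(x1 - x0), num(bar_h),
          layout$colors[[b$status]], b$status))
      }
    }

    es <- profile$element_status[[eid]]
    if (is.null(es)) {
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"12\" fill=\"#666666\" class=\"not-answered\">%s</text>",
        num(bar_x + bar_w + 8), num(y + 30), "not answered"))
    } else {
      v <- es$value
      if (categorical) {
        cats <- unlist(e$categories)
        pos <- bar_x + bar_w * (match(v, cats) - 0.5) / length(cats)
        label <- as.character(v)
      } else {
        lo <- e$range[[1L]]; hi <- e$range[[2L]]
        pos <- bar_x + bar_w * (v - lo) / (hi - lo)
        label <- format_value(v, integer = isTRUE(e$integer))
        if (!identical(layout$decimal_mark, ".")) {
          label <- gsub(".", layout$decimal_mark, label, fixed = TRUE)
        }
      }
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"13\" text-anchor=\"middle\" fill=\"#000000\" class=\"score-label\">%s</text>",
        num(pos), num(y + 8), xml_escape(label)))
      out <- c(out, sprintf(
        "<path d=\"M %s %s L %s %s L %s %s Z\" fill=\"#000000\" class=\"score-marker\"/>",
        num(pos - 6), num(y + 10), num(pos + 6), num(y + 10), num(pos), num(y + 14 + 2)))
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a static HTML report for a profile
#'
#' Writes `wheel.svg`, one `detail-<parameter>.svg` per parameter (every
#' icon has a click-through) and an `index.html` linking them.
#'
#' @param profile a `diag360_profile`.
#' @param config the matching `diag360_config`.
#' @param dir output directory (created if needed).
#' @param layout optional layout list.
#' @return `dir`, invisibly.
#' @export
render_report <- function(profile, config, dir, layout = NULL) {
  if (is.null(layout)) layout <- default_wheel_layout(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(render_wheel(profile, config, layout),
             file.path(dir, "wheel.svg"), sep = "")
  links <- character(0)
  for (pid in config$parameter_order) {
    fn <- sprintf("detail-%s.svg", pid)
    writeLines(render_detail(profile, pid, config, layout),
               file.path(dir, fn), sep = "")
    links <- c(links, sprintf("<li><a href=\"%s\">%s</a> — %s</li>", fn,
                              xml_escape(cfg_label(config$parameters[[pid]])),
                              profile$parameter_status[[pid]]))
  }
  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset=\"utf-8\"/><title>360 diagnosis</title></head><body>",
            sprintf("<h1>360&#176; diagnosis — patient %s (%s)</h1>",
                    xml_escape(profile$patient_id), xml_escape(profile$timepoint)),
            "<object data=\"wheel.svg\" type=\"image/svg+xml\" width=\"600\" height=\"600\"></object>",
            "<ul>", links, "</ul>", "</body></html>")
  writeLines(html, file.path(dir, "index.html"))
  invisible(dir)
}
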