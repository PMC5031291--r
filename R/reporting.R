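# Report generation: static local HTML pages, publication figures in up
# to five formats (PNG, JPG, SVG, EPS, PDF), parameter tables as CSV/TSV,
# and a minimal hierarchical XML phenotype record per condition.
#
# Report content is a pure function of the fits: rendering the same fits
# twice yields byte-identical tables and XML (the one timestamp lives in
# a single provenance field, injectable for reproducible output).

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

figure_device <- function(format, path, width = 7, height = 5) {
  switch(format,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    jpg = grDevices::jpeg(path, width = width, height = height,
                          units = "in", res = 150, quality = 92),
    svg = grDevices::svg(path, width = width, height = height),
    eps = grDevices::cairo_ps(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop_invalid_input(sprintf("unknown figure format '%s'", format))
  )
}

save_figure <- function(plot, stem, dir, formats) {
  files <- character(0)
  for (fmt in formats) {
    path <- file.path(dir, paste0(stem, ".", fmt))
    figure_device(fmt, path)
    print(plot)
    grDevices::dev.off()
    files <- c(files, path)
  }
  files
}

growth_curve_plot <- function(series, fit, condition, log_scale = FALSE,
                              bw = FALSE) {
  pts <- do.call(rbind, lapply(names(series), function(obs) {
    s <- series[[obs]]
    data.frame(time = s$times, mean = s$mean,
               sd = ifelse(is.na(s$sd), 0, s$sd), observable = obs)
  }))
  grid <- seq(min(pts$time), max(pts$time), length.out = 200)
  traj <- model_registry()[[fit$model_name]]$simulate(fit$estimates, grid)
  lines <- do.call(rbind, lapply(names(traj$values), function(obs) {
    data.frame(time = grid, value = traj$values[[obs]], observable = obs)
  }))
  lines <- lines[lines$observable %in% pts$observable, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_errorbar(
      data = pts,
      ggplot2::aes(x = .data$time, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd, group = .data$observable),
      width = 0.6, linewidth = 0.3) +
    ggplot2::labs(
      title = sprintf("%s: %s model", condition, fit$model_name),
      x = "time (h)",
      y = if (log_scale) "cell count (log scale)" else "cell count") +
    ggplot2::theme_bw()
  if (bw) {
    p <- p +
      ggplot2::geom_line(data = lines,
                         ggplot2::aes(x = .data$time, y = .data$value,
                                      linetype = .data$observable),
                         colour = "black") +
      ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = .data$time, y = .data$mean,
                                       shape = .data$observable),
                          colour = "black", size = 2)
  } else {
    p <- p +
      ggplot2::geom_line(data = lines,
                         ggplot2::aes(x = .data$time, y = .data$value,
                                      colour = .data$observable)) +
      ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = .data$time, y = .data$mean,
                                       colour = .data$observable), size = 2)
  }
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

format_num <- function(x, digits = 6) {
  ifelse(is.na(x), "N/A", formatC(x, digits = digits, format = "g"))
}

parameter_table <- function(fit, ci_level = 95) {
  ci <- t(vapply(seq_along(fit$estimates), function(i) {
    s <- fit$sem[[i]]
    if (is.na(s)) c(lower = NA_real_, upper = NA_real_)
    else confidence_interval(fit$estimates[[i]], s, ci_level)
  }, c(lower = 0, upper = 0)))
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             unit = unname(fit$units),
             sem = unname(fit$sem),
             ci_lower = ci[, "lower"], ci_upper = ci[, "upper"])
}

write_table_formats <- function(tab, stem, dir, digits = 12) {
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x)
    formatC(x, digits = digits, format = "g"))
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  utils::write.table(tab, tsv, row.names = FALSE, quote = FALSE,
                     sep = "\t", fileEncoding = "UTF-8")
  c(csv, tsv)
}

model_page_html <- function(fit, spec, condition, ci_level) {
  tab <- parameter_table(fit, ci_level)
  rows <- paste(apply(tab, 1L, function(r) sprintf(
    "<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>[%s, %s]</td></tr>",
    html_escape(r[["parameter"]]), format_num(as.numeric(r[["estimate"]])),
    html_escape(r[["unit"]]), format_num(as.numeric(r[["sem"]])),
    format_num(as.numeric(r[["ci_lower"]])),
    format_num(as.numeric(r[["ci_upper"]])))), collapse = "\n")
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>",
    sprintf("<title>%s - %s</title></head><body>\n",
            html_escape(condition), html_escape(fit$model_name)),
    sprintf("<h1>%s &mdash; %s model</h1>\n", html_escape(condition),
            html_escape(fit$model_name)),
    sprintf("<p>%s</p>\n", html_escape(spec$description)),
    sprintf("<p>Model equations (LaTeX): <code>%s</code></p>\n",
            html_escape(model_equation_latex(fit$model_name))),
    sprintf("<h2>Parameter estimates (%g %% CI)</h2>\n", ci_level),
    "<table border='1'><tr><th>parameter</th><th>estimate</th>",
    "<th>unit</th><th>SEM</th><th>CI</th></tr>\n", rows, "\n</table>\n",
    "<h2>Fit quality</h2>\n<ul>",
    sprintf("<li>WSSE: %s</li>", format_num(fit$wsse)),
    sprintf("<li>MAPE: %s %%</li>", format_num(fit$mape)),
    sprintf("<li>reduced &chi;&sup2;: %s</li>",
            format_num(fit$reduced_chi2)),
    sprintf("<li>data points: %d; parameters: %d</li>",
            fit$n_data, fit$n_parameters),
    sprintf("<li>converged: %s</li>", fit$converged),
    "</ul>\n<p><a href='index.html'>back to index</a></p>\n",
    "</body></html>\n")
}

#' Render a full analysis report
#'
#' Writes a self-contained local report directory: an index page ranking
#' every fitted model per condition by both MAPE and reduced chi-squared,
#' a page per (condition, model) with a layperson description, parameter
#' table (SEM + CI) and metrics, growth-curve figures (linear and
#' log-scale, colour and black-and-white), tables as CSV/TSV, and one
#' phenotype XML record per condition (best-ranked model).
#'
#' @param fits Named list: condition label -> list of `fit_result`s.
#' @param dataset The `experiment_dataset` that was fitted.
#' @param output_dir Report directory (created; must be writable).
#' @param formats Figure formats, subset of png/jpg/svg/eps/pdf.
#' @param ranking_metric Primary ranking metric for the index order.
#' @param ci_level Confidence level (percent) for parameter intervals.
#' @param timestamp Provenance timestamp string; fixed default keeps
#'   output byte-reproducible, pass `format(Sys.time())` for wall-clock.
#' @return A `report_bundle` (list of written paths), invisibly.
#' @export
render_report <- function(fits, dataset, output_dir,
                          formats = c("png", "svg"),
                          ranking_metric = c("reduced_chi2", "mape"),
                          ci_level = 95, timestamp = "unset") {
  ranking_metric <- match.arg(ranking_metric)
  if (length(fits) == 0L ||
      !any(unlist(lapply(fits, lapply, `[[`, "converged")))) {
    stop_invalid_input("need at least one converged fit to render a report")
  }
  ok <- tryCatch({
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(output_dir, 2L) == 0L
  }, error = function(e) FALSE)
  if (!ok) {
    stop_cellpopfit("io_error",
                    sprintf("output directory '%s' is not writable",
                            output_dir))
  }
  registry <- model_registry()
  cond_by_label <- stats::setNames(dataset$conditions,
                                   vapply(dataset$conditions, `[[`, "",
                                          "label"))
  bundle <- list(index = file.path(output_dir, "index.html"),
                 pages = character(0), figures = character(0),
                 tables = character(0), xml = character(0))
  index_sections <- character(0)

  for (lab in names(fits)) {
    ranked <- rank_models(fits[[lab]], ranking_metric)
    ranked_mape <- rank_models(fits[[lab]], "mape")
    series <- suppressWarnings(aggregate_condition(cond_by_label[[lab]]))
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lab)

    rows <- vapply(seq_along(ranked), function(i) {
      f <- ranked[[i]]
      page <- sprintf("model_%s_%s.html", safe, f$model_name)
      sprintf(paste0("<tr><td>%d</td><td><a href='%s'>%s</a></td>",
                     "<td>%s</td><td>%s</td><td>%d</td><td>%s</td></tr>"),
              i, page, html_escape(f$model_name),
              format_num(f$rank_scores$reduced_chi2),
              format_num(f$rank_scores$mape), f$n_parameters,
              if (f$converged) "yes" else "no")
    }, "")
    mape_order <- paste(vapply(ranked_mape, `[[`, "", "model_name"),
                        collapse = " &lt; ")
    index_sections <- c(index_sections, paste0(
      sprintf("<h2>%s</h2>\n", html_escape(lab)),
      sprintf("<table border='1'><tr><th>rank (%s)</th><th>model</th>",
              ranking_metric),
      "<th>reduced &chi;&sup2;</th><th>MAPE (%)</th>",
      "<th>parameters</th><th>converged</th></tr>\n",
      paste(rows, collapse = "\n"), "\n</table>\n",
      sprintf("<p>Ranking by MAPE: %s</p>\n", mape_order),
      sprintf(paste0("<p>Figures: <a href='growth_%s_linear.%s'>linear</a>,",
                     " <a href='growth_%s_log.%s'>log</a>,",
                     " <a href='growth_%s_linear_bw.%s'>black &amp; white</a>",
                     "</p>\n"),
              safe, formats[1L], safe, formats[1L], safe, formats[1L])))

    for (f in ranked) {
      page <- file.path(output_dir,
                        sprintf("model_%s_%s.html", safe, f$model_name))
      writeLines(model_page_html(f, registry[[f$model_name]], lab, ci_level),
                 page, useBytes = TRUE)
      bundle$pages <- c(bundle$pages, page)
      bundle$tables <- c(bundle$tables, write_table_formats(
        parameter_table(f, ci_level),
        sprintf("parameters_%s_%s", safe, f$model_name), output_dir))
    }

    best <- ranked[[1L]]
    if (best$converged) {
      bundle$figures <- c(
        bundle$figures,
        save_figure(growth_curve_plot(series, best, lab, FALSE, FALSE),
                    sprintf("growth_%s_linear", safe), output_dir, formats),
        save_figure(growth_curve_plot(series, best, lab, TRUE, FALSE),
                    sprintf("growth_%s_log", safe), output_dir, formats),
        save_figure(growth_curve_plot(series, best, lab, FALSE, TRUE),
                    sprintf("growth_%s_linear_bw", safe), output_dir,
                    formats))
      xml_path <- file.path(output_dir,
                            sprintf("phenotype_%s.xml", safe))
      write_phenotype_xml(best, dataset$metadata, dataset$user_info,
                          xml_path, timestamp = timestamp)
      bundle$xml <- c(bundle$xml, xml_path)
    }

    metrics_tab <- do.call(rbind, lapply(ranked, function(f) data.frame(
      model = f$model_name, wsse = f$wsse, mape = f$mape,
      reduced_chi2 = f$reduced_chi2, n_data = f$n_data,
      n_parameters = f$n_parameters, converged = f$converged)))
    bundle$tables <- c(bundle$tables, write_table_formats(
      metrics_tab, sprintf("metrics_%s", safe), output_dir))
  }

  index_html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>",
    "<title>Growth model calibration report</title></head><body>\n",
    "<h1>Growth model calibration report</h1>\n",
    sprintf("<p>Cell line: %s; media: %s</p>\n",
            html_escape(dataset$metadata$cell_line_name %||% "(unnamed)"),
            html_escape(dataset$metadata$media %||% "(unspecified)")),
    sprintf("<p>Generated: %s</p>\n", html_escape(timestamp)),
    paste(index_sections, collapse = "\n"),
    "</body></html>\n")
  writeLines(index_html, bundle$index, useBytes = TRUE)
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

#' Dose-response panels for one drug
#'
#' Three panels against dose: net growth rate (birth - death), birth rate
#' and death rate, each with SEM error bars. This is the view that
#' separates cytostatic from cytotoxic action: a falling net rate alone
#' cannot distinguish suppressed birth from increased death.
#'
#' Plotted values are read directly from the fit results (no
#' recomputation).
#'
#' @param fits List of converged birth-death-clearance `fit_result`s, one
#'   per dose.
#' @param doses Numeric dose vector aligned with `fits`.
#' @param drug_name Label for titles.
#' @return Named list of ggplot objects: `net`, `birth`, `death` (birth
#'   and death `NULL`, with a warning, if the fits carry no death rate).
#' @export
plot_dose_response <- function(fits, doses, drug_name = "drug") {
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (sum(conv) < 2L) {
    stop_invalid_input("need converged fits at >= 2 doses")
  }
  fits <- fits[conv]; doses <- doses[conv]
  has_death <- all(vapply(fits, function(f)
    all(c("birth_rate", "death_rate") %in% names(f$estimates)), TRUE))
  get <- function(f, p) if (p %in% names(f$estimates)) f$estimates[[p]] else NA
  gsem <- function(f, p) if (p %in% names(f$sem)) f$sem[[p]] else NA
  df <- data.frame(
    dose = doses,
    birth = vapply(fits, get, 1, "birth_rate"),
    death = vapply(fits, get, 1, "death_rate"),
    birth_sem = vapply(fits, gsem, 1, "birth_rate"),
    death_sem = vapply(fits, gsem, 1, "death_rate"))
  if (has_death) {
    df$net <- df$birth - df$death
    df$net_sem <- sqrt(df$birth_sem^2 + df$death_sem^2)
  } else {
    warning("fits carry no separate death rate; returning net-rate panel only")
    df$net <- vapply(fits, get, 1, "growth_rate")
    df$net_sem <- vapply(fits, gsem, 1, "growth_rate")
  }
  panel <- function(y, ysem, what) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data[[y]])) +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data[[y]] - .data[[ysem]],
        ymax = .data[[y]] + .data[[ysem]]), width = 0.05) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(title = sprintf("%s: %s rate vs dose", drug_name, what),
                    x = "dose (concentration units, log scale)",
                    y = sprintf("%s rate (1/h)", what)) +
      ggplot2::theme_bw()
  }
  list(net = panel("net", "net_sem", "net growth"),
       birth = if (has_death) panel("birth", "birth_sem", "birth") else NULL,
       death = if (has_death) panel("death", "death_sem", "death") else NULL)
}

#' Write a phenotype record as XML
#'
#' A minimal hierarchical digital-cell-line record: cell-line identity,
#' the calibrated model, every parameter with value, units and SEM, fit
#' metrics, and provenance (tool version, timestamp, user). Values are
#' serialised with 17 significant digits so the record round-trips
#' bit-exactly through [read_phenotype_xml()].
#'
#' @param best_fit A converged `fit_result`.
#' @param metadata,user_info Lists as carried by an `experiment_dataset`.
#' @param path Output XML path (parent directories created).
#' @param timestamp Provenance timestamp string (a fixed value keeps the
#'   file byte-reproducible).
#' @return `path`, invisibly.
#' @export
write_phenotype_xml <- function(best_fit, metadata = list(),
                                user_info = list(), path,
                                timestamp = "unset") {
  if (!isTRUE(best_fit$converged)) {
    stop_invalid_input("phenotype XML requires a converged fit")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  doc <- xml2::xml_new_root("cell_phenotype")
  cl <- xml2::xml_add_child(doc, "cell_line")
  xml2::xml_set_attr(cl, "name", metadata$cell_line_name %||% "unknown")
  xml2::xml_set_attr(cl, "media", metadata$media %||% "")
  model <- xml2::xml_add_child(doc, "model")
  xml2::xml_set_attr(model, "name", best_fit$model_name)
  params <- xml2::xml_add_child(model, "parameters")
  for (p in names(best_fit$estimates)) {
    node <- xml2::xml_add_child(params, "parameter")
    xml2::xml_set_attr(node, "name", p)
    xml2::xml_set_attr(node, "units", best_fit$units[[p]])
    xml2::xml_set_attr(node, "value", fmt(best_fit$estimates[[p]]))
    xml2::xml_set_attr(node, "sem", fmt(best_fit$sem[[p]]))
  }
  metrics <- xml2::xml_add_child(model, "metrics")
  xml2::xml_set_attr(metrics, "wsse", fmt(best_fit$wsse))
  xml2::xml_set_attr(metrics, "mape_percent", fmt(best_fit$mape))
  xml2::xml_set_attr(metrics, "reduced_chi_squared", fmt(best_fit$reduced_chi2))
  xml2::xml_set_attr(metrics, "n_data", as.character(best_fit$n_data))
  xml2::xml_set_attr(metrics, "n_parameters",
                     as.character(best_fit$n_parameters))
  prov <- xml2::xml_add_child(doc, "provenance")
  xml2::xml_set_attr(prov, "tool", "cellpopfit")
  xml2::xml_set_attr(prov, "tool_version",
                     as.character(utils::packageVersion("cellpopfit")))
  xml2::xml_set_attr(prov, "timestamp", timestamp)
  xml2::xml_set_attr(prov, "user", user_info$name %||% "")
  xml2::xml_set_attr(prov, "contact", user_info$contact %||% "")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a phenotype XML record
#'
#' @param path XML path written by [write_phenotype_xml()].
#' @return List with `model_name`, `estimates`, `sem`, `units`, `metrics`.
#' @export
read_phenotype_xml <- function(path) {
  doc <- xml2::read_xml(path)
  params <- xml2::xml_find_all(doc, ".//parameter")
  nm <- xml2::xml_attr(params, "name")
  metrics <- xml2::xml_find_first(doc, ".//metrics")
  list(
    model_name = xml2::xml_attr(xml2::xml_find_first(doc, ".//model"),
                                "name"),
    estimates = stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                                nm),
    sem = stats::setNames(as.numeric(xml2::xml_attr(params, "sem")), nm),
    units = stats::setNames(xml2::xml_attr(params, "units"), nm),
    metrics = list(
      wsse = as.numeric(xml2::xml_attr(metrics, "wsse")),
      mape = as.numeric(xml2::xml_attr(metrics, "mape_percent")),
      reduced_chi2 = as.numeric(xml2::xml_attr(metrics,
                                               "reduced_chi_squared")),
      n_data = as.integer(xml2::xml_attr(metrics, "n_data")),
      n_parameters = as.integer(xml2::xml_attr(metrics, "n_parameters"))))
}
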