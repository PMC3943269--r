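#' Export a neighborhood choropleth as GeoJSON
#'
#' Writes a FeatureCollection of unit-square polygons (one per lattice cell)
#' with the given value as a feature property, suitable for any GeoJSON
#' viewer.
#'
#' @param graph a [nbhd_graph()] with lattice cells.
#' @param values numeric vector named by node id or in `graph$node_ids`
#'   order.
#' @param path output file.
#' @param property property name for the value.
#' @return `path`, invisibly.
#' @export
write_choropleth_geojson <- function(graph, values, path, property = "effect") {
  if (is.null(graph$cells)) {
    abort_recwalk("graph has no lattice cells; cannot export polygons.",
                  "invalid_argument")
  }
  if (!is.null(names(values))) values <- values[as.character(graph$node_ids)]
  cells <- graph$cells
  features <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- cells$col[i] - 1; x1 <- cells$col[i]
    y0 <- -cells$row[i]; y1 <- -(cells$row[i] - 1)
    props <- list(node_id = cells$node_id[i])
    props[[property]] <- round(as.numeric(values[i]), 6)
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(list(c(x0, y0), c(x1, y0), c(x1, y1),
                                c(x0, y1), c(x0, y0)))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  }
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, body), collapse = "\n")
}

# all pipeline artifacts; the report text is deterministic given the seed
# (timings and environment details deliberately excluded)
write_report_artifacts <- function(report, dir) {
  cfg <- report$config

  utils::write.csv(report$decomposition, file.path(dir, "decomposition.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pretest, file.path(dir, "pretest.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  if (nrow(report$interactions)) {
    utils::write.csv(report$interactions, file.path(dir, "interactions.csv"),
                     row.names = FALSE)
  }
  for (oc in names(report$final)) {
    utils::write.csv(report$final[[oc]]$or_table,
                     file.path(dir, sprintf("final_or_%s.csv", oc)),
                     row.names = FALSE)
    if (!is.null(report$risk[[oc]])) {
      utils::write.csv(report$risk[[oc]]$boot,
                       file.path(dir, sprintf("risk_score_%s.csv", oc)),
                       row.names = FALSE)
    }
  }

  # choropleths: posterior mean spatial (CAR) effects before and after
  # environmental adjustment, binary outcome
  map_value <- function(fit) {
    eff <- neighborhood_effects(fit)
    v <- setNames(rep(NA_real_, n_nodes(report$graph)),
                  report$graph$node_ids)
    v[as.character(eff$neighborhood_id)] <- eff$v
    v
  }
  if (!is.null(report$graph$cells)) {
    write_choropleth_geojson(report$graph, map_value(report$stage2$binary$fit),
                             file.path(dir, "map_structured_pre_env.geojson"))
    write_choropleth_geojson(report$graph, map_value(report$final$binary$fit),
                             file.path(dir, "map_structured_post_env.geojson"))
  }

  # markdown report
  lines <- c(
    "# Recreational walking pipeline report", "",
    sprintf("Cohort: %d individuals in %d neighborhoods.", report$cohort_n,
            n_nodes(report$graph)), "",
    "## Sample description", "", md_table(report$descriptives, 1), "",
    "## Between-neighborhood variance decomposition", "",
    md_table(report$decomposition), "",
    "## Retained individual and weather variables", "",
    paste(vapply(names(report$selection), function(oc) {
      sprintf("- %s: %s", oc,
              if (length(report$selection[[oc]])) {
                paste(report$selection[[oc]], collapse = ", ")
              } else "(none)")
    }, character(1)), collapse = "\n"), "",
    "## Environmental pretests (one at a time)", "",
    md_table(report$pretest), ""
  )
  for (oc in names(report$final)) {
    lines <- c(lines,
               sprintf("## Final model (%s outcome)", oc), "",
               sprintf("Retained environmental variables: %s",
                       if (length(report$final[[oc]]$retained_env)) {
                         paste(report$final[[oc]]$retained_env, collapse = ", ")
                       } else "(none)"), "",
               md_table(report$final[[oc]]$or_table), "")
  }
  if (nrow(report$interactions)) {
    lines <- c(lines, "## Weather x environment interactions", "",
               md_table(report$interactions), "")
  } else {
    lines <- c(lines, "## Weather x environment interactions", "",
               "No interactions tested (no retained environmental variables).", "")
  }
  lines <- c(lines, "## Environmental risk score", "")
  for (oc in names(report$risk)) {
    if (!is.null(report$risk[[oc]])) {
      lines <- c(lines, sprintf("### %s outcome", oc), "",
                 md_table(report$risk[[oc]]$boot), "",
                 report$risk[[oc]]$sentence, "")
    }
  }
  writeLines(lines, file.path(dir, "report.md"))

  # provenance manifest
  cfg_plain <- unclass(cfg)
  cfg_plain$control <- unclass(cfg_plain$control)
  cfg_plain$priors <- unclass(cfg_plain$priors)
  if (!is.null(cfg_plain$generator)) {
    cfg_plain$generator <- unclass(cfg_plain$generator)
  }
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, null = "null",
                               force = TRUE)
  cfg_path <- file.path(dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("recwalk")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    report_md5 = unname(tools::md5sum(file.path(dir, "report.md"))),
    artifacts = list.files(dir)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
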