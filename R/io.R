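#' Write a cohort table to TSV with a JSON side-car
#'
#' The TSV holds subjects as rows (first column `subject_id`, missing
#' values as `NA`); the side-car carries the per-measurement annotations,
#' the subject labels, the planted ground-truth assignment and the
#' generator fingerprint, so the pair round-trips through
#' [read_cohort()].
#'
#' @param table a `cohort_table`.
#' @param tsv_path,sidecar_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(table, tsv_path, sidecar_path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- data.frame(subject_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  side <- list(annotations = table$annotations, labels = table$labels,
               planted = as.list(table$planted),
               generator = table$generator)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv_path, sidecar_path))
}

#' Read a cohort table written by [write_cohort()]
#'
#' Accepts both Unix and Windows line endings; every value column must
#' be annotated in the side-car, and unknown columns are rejected by
#' name.
#'
#' @param tsv_path,sidecar_path input file paths.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(tsv_path, sidecar_path) {
  if (!file.exists(tsv_path)) stop("no such file: ", tsv_path)
  if (!file.exists(sidecar_path)) stop("no such file: ", sidecar_path)
  df <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  ann <- as.data.frame(side$annotations, stringsAsFactors = FALSE)
  value_cols <- setdiff(colnames(df), "subject_id")
  unknown <- setdiff(value_cols, ann$measurement)
  if (length(unknown) > 0) {
    stop("column '", unknown[1], "' is not annotated in the side-car")
  }
  absent <- setdiff(ann$measurement, value_cols)
  if (length(absent) > 0) {
    stop("annotated measurement '", absent[1], "' missing from the table")
  }
  values <- as.matrix(df[, ann$measurement, drop = FALSE])
  rownames(values) <- df$subject_id
  labels <- as.data.frame(side$labels, stringsAsFactors = FALSE)
  labels$status <- factor(labels$status,
                          levels = c("healthy", "mild", "moderate",
                                     "severe"))
  planted <- unlist(side$planted)
  structure(list(values = values, missing = is.na(values),
                 annotations = ann, labels = labels,
                 planted = planted,
                 generator = side$generator),
            class = "cohort_table")
}

#' Write a composite matrix to TSV plus JSON provenance
#'
#' @param m a `composite_matrix`.
#' @param tsv_path,provenance_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_composite <- function(m, tsv_path, provenance_path) {
  stopifnot(inherits(m, "composite_matrix"))
  df <- data.frame(subject_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(column_means = as.list(m$column_means),
         column_sds = as.list(m$column_sds),
         provenance = m$provenance, dropped = m$dropped),
    provenance_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv_path, provenance_path))
}

#' Export a Mapper graph
#'
#' GraphML (node attributes: size, cluster id, mean of each overlaid
#' parameter) via igraph, or a plain JSON rendering of nodes and edges.
#'
#' @param g a `mapper_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @param m optional `composite_matrix` whose column means are overlaid
#'   per node.
#' @param report optional `cluster_report` supplying node cluster ids.
#' @return invisibly, `path`.
#' @export
write_mapper_graph <- function(g, path, format = c("graphml", "json"),
                               m = NULL, report = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(g, "mapper_graph"))
  node_cluster <- NULL
  if (!is.null(report)) {
    node_cluster <- vapply(g$nodes, function(s) {
      labs <- report$membership[s]
      names(which.max(table(labs)))
    }, character(1))
  }
  if (format == "graphml") {
    ig <- as_igraph(g)
    igraph::V(ig)$name <- paste0("n", seq_along(g$nodes))
    if (!is.null(node_cluster)) igraph::V(ig)$cluster <- node_cluster
    if (!is.null(m)) {
      for (p in colnames(m$values)) {
        igraph::vertex_attr(ig, paste0("mean_", p)) <-
          vapply(g$nodes, function(s) mean(m$values[s, p]), numeric(1))
      }
    }
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    jsonlite::write_json(
      list(nodes = lapply(seq_along(g$nodes), function(i) {
        list(id = i, subjects = g$nodes[[i]],
             cluster = if (is.null(node_cluster)) NULL
                       else node_cluster[i])
      }),
      edges = apply(g$edges, 1, as.list)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Export a Bayesian network
#'
#' GraphML or DOT with per-arc strength and sign class attributes.
#'
#' @param net a `bayes_network`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return invisibly, `path`.
#' @export
write_bayes_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "bayes_network"))
  ig <- igraph::make_empty_graph(n = length(net$nodes), directed = TRUE)
  igraph::V(ig)$name <- net$nodes
  if (nrow(net$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(match(net$edges$from, net$nodes),
                                      match(net$edges$to, net$nodes)))
    if (!is.null(net$edges$strength)) {
      igraph::E(ig)$strength <- net$edges$strength
    }
    if (!is.null(net$edges$sign_class)) {
      igraph::E(ig)$sign_class <- net$edges$sign_class
    }
  }
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles all stage options with a master seed; every stage derives its
#' own stream with [stage_seed()], so skipping a stage never perturbs
#' the others.
#'
#' @param generator a [generator_config()] (ignored when `input_tsv`
#'   points at an existing cohort).
#' @param input_tsv,input_sidecar optional paths to a cohort on disk.
#' @param alpha Shapiro-Wilk level for the scale decision.
#' @param composite a [composite_spec()].
#' @param cover a [cover_spec()].
#' @param cluster_alpha,cluster_adjust KS screen options for
#'   [extract_clusters()].
#' @param restarts,max_parents Bayesian-network search options.
#' @param rule a [subtype_rule()].
#' @param seed master seed.
#' @param skip character vector of stage names to skip (among
#'   `"stats"`, `"mapper"`, `"bna"`, `"subtype"`).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_tsv = NULL, input_sidecar = NULL,
                            alpha = 0.05,
                            composite = composite_spec(),
                            cover = cover_spec(),
                            cluster_alpha = 0.05,
                            cluster_adjust = "bh",
                            restarts = 3L, max_parents = 3L,
                            rule = subtype_rule(),
                            seed = 1L, skip = character(0)) {
  structure(list(generator = generator, input_tsv = input_tsv,
                 input_sidecar = input_sidecar, alpha = alpha,
                 composite = composite, cover = cover,
                 cluster_alpha = cluster_alpha,
                 cluster_adjust = cluster_adjust,
                 restarts = restarts, max_parents = max_parents,
                 rule = rule, seed = as.integer(seed), skip = skip),
            class = "pipeline_config")
}

#' Run the full stratification pipeline
#'
#' Stages in analysis order: cohort (simulate or read), preprocessing
#' (scale, impute, composite, normalize), the severity-stratified test
#' battery, Bayesian network analysis, topological (Mapper) analysis
#' and the sputum subtype report. When `out_dir` is given, every
#' artifact is written (TSV/JSON/GraphML) together with a manifest
#' recording the configuration and seeds; identical config and seed
#' reproduce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `cohort`, `composite`, `stats`, `bayesnet`,
#'   `mapper`, `subtype` (skipped stages are `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, skip = config$skip,
                   stages = character(0),
                   timestamp = format(Sys.time(), tz = "UTC"))
  run_stage <- function(name, fun) {
    if (name %in% config$skip) return(NULL)
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  cohort <- run_stage("cohort", function() {
    if (!is.null(config$input_tsv)) {
      read_cohort(config$input_tsv, config$input_sidecar)
    } else {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "simulate")
      generate_cohort(gen)
    }
  })
  composite <- run_stage("preprocess", function() {
    preprocess_cohort(cohort, alpha = config$alpha,
                      spec = config$composite)
  })
  stats_tab <- run_stage("stats", function() severity_battery(composite))
  bn <- run_stage("bna", function() {
    bayes_network_run(composite, restarts = config$restarts,
                      seed = stage_seed(config$seed, "bna"),
                      max_parents = config$max_parents)
  })
  mp <- run_stage("mapper", function() {
    mapper_run(composite, spec = config$cover,
               alpha = config$cluster_alpha,
               adjust = config$cluster_adjust)
  })
  st <- run_stage("subtype", function() {
    subtype_report(cohort, rule = config$rule)
  })
  result <- list(cohort = cohort, composite = composite,
                 stats = stats_tab, bayesnet = bn, mapper = mp,
                 subtype = st, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(out_dir, ...)
    write_cohort(cohort, fp("cohort.tsv"), fp("cohort.json"))
    write_composite(composite, fp("composite.tsv"),
                    fp("composite_provenance.json"))
    if (!is.null(stats_tab)) {
      utils::write.table(stats_tab, fp("stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bn)) {
      write_bayes_network(bn, fp("bayesnet.graphml"))
      write_bayes_network(bn, fp("bayesnet.dot"), format = "dot")
    }
    if (!is.null(mp)) {
      write_mapper_graph(mp$graph, fp("mapper.graphml"), m = composite,
                         report = mp$report)
      write_mapper_graph(mp$graph, fp("mapper.json"), format = "json",
                         report = mp$report)
    }
    if (!is.null(st)) {
      utils::write.table(st$table, fp("subtype.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
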