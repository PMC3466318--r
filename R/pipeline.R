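#' Write a TSV with a provenance header
#'
#' All pipeline outputs are UTF-8, tab-delimited tables with a header row,
#' preceded by `#`-prefixed provenance comments (package version, seed,
#' input hashes). Readers throughout the package skip `#` lines.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed seed recorded in the header (optional).
#' @param inputs named character vector of input paths to hash (optional).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NULL, inputs = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# archevo ", as.character(packageVersion("archevo"))),
             con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(inputs)) {
    for (nm in names(inputs)) {
      h <- tryCatch(unname(tools::md5sum(inputs[[nm]])),
                    error = function(e) NA_character_)
      writeLines(paste0("# input ", nm, ": ", inputs[[nm]], " md5:", h), con)
    }
  }
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a flat key-value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; whitespace is
#' trimmed. Values are returned as strings (callers coerce).
#'
#' @param path config file path.
#' @return Named list of strings.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Run the full analysis pipeline over files on disk
#'
#' Stages: census (hit table -> census + summary), phylo (species tree +
#' presence profiles -> origin hypotheses per architecture), ecostats
#' (census sub-families x eco profile -> correlation battery), enrich
#' (annotations + DAG -> enrichment table). Stages whose inputs are not
#' configured are skipped; a stage failure aborts with an error naming the
#' stage. Every output carries a provenance header; per-stage record counts
#' go to `message()` (suppressible with `quiet = TRUE`).
#'
#' @param config named list (see [read_pipeline_config()]) or path to a
#'   config file. Recognised keys: `hits`, `anchor` (default the LuxR
#'   anchor), `species_tree`, `eco`, `scheme`, `annotations`, `dag`,
#'   `enrich_group`, `alpha` (default 0.05), `fdr` (default 0.05), `seed`
#'   (default 1), `out_dir` (required).
#' @param quiet suppress progress messages.
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  if (is.null(config$out_dir)) stop("config error: out_dir is required",
                                    call. = FALSE)
  for (key in c("hits", "species_tree", "eco", "scheme", "annotations",
                "dag")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("config error: ", key, " file not found: ", config[[key]],
           call. = FALSE)
    }
  }
  alpha <- as.numeric(config$alpha %||% 0.05)
  fdr <- as.numeric(config$fdr %||% 0.05)
  seed <- as.integer(config$seed %||% 1)
  if (!(alpha > 0 && alpha < 1) || !(fdr > 0 && fdr < 1)) {
    stop("config error: alpha and fdr must lie in (0, 1)", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cens <- NULL
  if (!is.null(config$hits)) {
    cens <- stage("census", {
      hits <- parse_domain_hits(config$hits)
      anchor <- config$anchor %||% anchor_accession()
      archs <- classify_all(hits, anchor_acc = anchor)
      cens <- build_census(archs)
      sm <- census_summary(cens)
      outputs$census <- write_tsv(cens, file.path(config$out_dir,
                                                   "census.tsv"),
                                   seed = seed, inputs = c(hits = config$hits))
      summary_df <- data.frame(
        statistic = c("grand_total", "n_species", "percent_multidomain"),
        value = c(sm$grand_total, sm$n_species, sm$percent_multidomain))
      outputs$census_summary <- write_tsv(
        summary_df, file.path(config$out_dir, "census_summary.tsv"),
        seed = seed)
      say("census: ", sm$grand_total, " proteins, ", sm$n_species, " species")
      cens
    })
  }

  if (!is.null(config$species_tree) && !is.null(cens)) {
    stage("phylo", {
      tr <- read_newick(config$species_tree)
      profs <- census_presence_profiles(cens, tr$tip.label)
      rows <- lapply(names(profs), function(a) {
        hy <- evaluate_origin_hypotheses(tr, profs[[a]])
        top <- hy[1, , drop = FALSE]
        cbind(architecture = a, top)
      })
      res <- do.call(rbind, rows)
      outputs$origins <- write_tsv(res, file.path(config$out_dir,
                                                   "origin_hypotheses.tsv"),
                                    seed = seed)
      say("phylo: ", nrow(res), " architectures scored")
    })
  }

  if (!is.null(config$eco) && !is.null(cens)) {
    stage("ecostats", {
      raw <- read.delim(config$eco, stringsAsFactors = FALSE,
                        comment.char = "#")
      eco <- if (!is.null(config$scheme)) {
        ordinal_encode(raw, read_coding_scheme(config$scheme))
      } else raw
      battery <- correlation_battery(census_subfamilies(cens), eco,
                                     alpha = alpha)
      outputs$battery <- write_tsv(battery,
                                    file.path(config$out_dir, "battery.tsv"),
                                    seed = seed, inputs = c(eco = config$eco))
      say("ecostats: ", nrow(battery), " cells")
    })
  }

  if (!is.null(config$annotations) && !is.null(config$enrich_group)) {
    stage("enrich", {
      ann <- read.delim(config$annotations, stringsAsFactors = FALSE,
                        comment.char = "#")
      dag <- if (!is.null(config$dag)) {
        read.delim(config$dag, stringsAsFactors = FALSE, comment.char = "#")
      } else NULL
      res <- enrich_terms(ann, group = config$enrich_group, dag = dag,
                          fdr = fdr)
      outputs$enrichment <- write_tsv(res, file.path(config$out_dir,
                                                      "enrichment.tsv"),
                                       seed = seed,
                                       inputs = c(annotations =
                                                    config$annotations))
      say("enrich: ", sum(res$significant), " significant of ", nrow(res),
          " terms")
    })
  }
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
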