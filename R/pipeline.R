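# End-to-end driver: composition screen -> distances (+SEs) -> gap
# detection -> delimitation scenarios -> NJ/rooting -> strict-clock dating.
# Two first-class input modes: an aligned FASTA (distances computed), or a
# published combined distance table (percent units, no sequences).

#' Pipeline configuration
#'
#' Exactly one of `fasta` and `matrix_fixture` must be supplied.
#'
#' @param fasta path to an aligned FASTA (fraction-unit distances computed).
#' @param matrix_fixture path to a combined printed distance table (percent
#'   units; see [read_printed_matrix()]). `matrix_se` optionally points to
#'   the parallel SE table.
#' @param metadata path to the specimen metadata TSV.
#' @param matrix_se optional SE table path for fixture mode.
#' @param models distance models to compute/extract (subset of `"K2P"`, `"p"`;
#'   the first is used for delimitation and the tree).
#' @param policy,coverage deletion policy for FASTA mode.
#' @param B bootstrap pseudoreplicates (FASTA mode; default 500).
#' @param seed integer seed (bootstrap and clock draws).
#' @param top_k candidate gaps to delimit under.
#' @param region_set path to a region-set file, or a character vector.
#' @param clock a [clock_config()].
#' @param outdir output directory.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, matrix_fixture = NULL, metadata = NULL,
                            matrix_se = NULL, models = c("K2P", "p"),
                            policy = "partial", coverage = 0.95, B = 500L,
                            seed = 1L, top_k = 2L, region_set = NULL,
                            clock = clock_config(), outdir = "barcodegap_out") {
  if (is.null(fasta) == is.null(matrix_fixture))
    bg_error("supply exactly one of 'fasta' and 'matrix_fixture'",
             "barcodegap_config_error")
  models <- match.arg(models, c("K2P", "p"), several.ok = TRUE)
  structure(list(fasta = fasta, matrix_fixture = matrix_fixture,
                 matrix_se = matrix_se, metadata = metadata, models = models,
                 policy = policy, coverage = coverage, B = as.integer(B),
                 seed = as.integer(seed), top_k = as.integer(top_k),
                 region_set = region_set, clock = clock, outdir = outdir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "outdir")]), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full delimitation pipeline
#'
#' Stages, in order: composition screen (FASTA mode; skipped with a log note
#' in fixture mode), pairwise distances with bootstrap SEs, barcoding-gap
#' detection, delimitation scenarios, NJ tree with rooting (outgroup if
#' metadata has outgroups, else midpoint), and strict-clock dating of the
#' ultrametricized tree. Every output file carries a provenance header
#' (package version, seed, config hash), and a log records counts at each
#' stage. A stage failure aborts with a diagnostic naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report bundle: a list with `composition`,
#'   `distances`, `gaps`, `scenarios`, `tree`, `dated`, `files`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$fasta, config$matrix_fixture, config$matrix_se,
              config$metadata)) {
    if (!is.null(p) && !file.exists(p))
      bg_error(sprintf("input file not found: %s", p), "barcodegap_io_error")
  }
  rs <- config$region_set
  if (is.character(rs) && length(rs) == 1L && file.exists(rs))
    rs <- read_region_set(rs)
  md <- if (!is.null(config$metadata)) read_metadata(config$metadata) else NULL

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  prov <- c(sprintf("barcodegap %s", as.character(utils::packageVersion("barcodegap"))),
            sprintf("seed: %d", config$seed),
            sprintf("config: %s", config_hash(config)))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  files <- list()
  bundle <- list()

  # -- composition screen ----------------------------------------------------
  if (!is.null(config$fasta)) {
    run_stage("composition", {
      aln <- read_fasta(config$fasta, require_aligned = TRUE, metadata = md)
      comp <- composition(aln)
      files$composition <- file.path(config$outdir, "composition.tsv")
      write_composition_tsv(comp, files$composition)
      bundle$composition <- comp
      if (!is.null(md) && any(md$group == "outgroup")) {
        scr <- screen_outgroups(aln)
        bundle$composition_screen <- scr
        logf("composition", sprintf("%d outgroup value(s) flagged", sum(scr$flagged)))
      } else {
        logf("composition", sprintf("%d sequences profiled", nrow(comp)))
      }
      bundle$alignment <- aln
    })
  } else {
    logf("composition", "skipped (fixture mode: no sequences)")
  }

  # -- distances -------------------------------------------------------------
  run_stage("distances", {
    if (!is.null(config$fasta)) {
      dms <- lapply(config$models, function(m)
        bootstrap_se(bundle$alignment, model = m, policy = config$policy,
                     coverage = config$coverage, B = config$B, seed = config$seed))
      names(dms) <- config$models
    } else {
      fix <- read_printed_matrix(config$matrix_fixture, se_path = config$matrix_se)
      dms <- fix[intersect(config$models, names(fix))]
    }
    for (m in names(dms)) {
      files[[paste0("dist_", m)]] <- file.path(config$outdir,
                                                sprintf("distances_%s.csv", m))
      write_distance_csv(dms[[m]], files[[paste0("dist_", m)]], header = prov)
    }
    bundle$distances <- dms
    logf("distances", sprintf("%d matrix/matrices (%s), %d taxa",
                              length(dms), paste(names(dms), collapse = ", "),
                              length(dms[[1L]]$labels)))
  })
  main <- bundle$distances[[config$models[[1L]]]]

  # -- gaps ------------------------------------------------------------------
  run_stage("gaps", {
    gaps <- find_gaps(main, top_k = config$top_k)
    files$histogram <- file.path(config$outdir, "distance_histogram.csv")
    write_gap_histogram(gaps, files$histogram)
    bundle$gaps <- gaps
    tg <- top_gaps(gaps)
    logf("gaps", sprintf("%d candidate gap(s); widest (%.4g, %.4g)",
                         nrow(tg), tg$lo[1L], tg$hi[1L]))
  })

  # -- delimitation scenarios ------------------------------------------------
  run_stage("delimit", {
    scen <- delimit_under_gaps(main, bundle$gaps, metadata = md, region_set = rs)
    bundle$scenarios <- scen
    for (i in seq_along(scen$partitions)) {
      f <- file.path(config$outdir, sprintf("partition_gap%d.tsv", i))
      files[[sprintf("partition_%d", i)]] <- f
      write_partition_tsv(scen$partitions[[i]], f, metadata = md)
    }
    files$scenarios <- file.path(config$outdir, "scenario_report.json")
    jsonlite::write_json(list(provenance = prov, units = main$units,
                              model = main$model, scenarios = scen$scenarios),
                         files$scenarios, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    logf("delimit", paste(sprintf("gap %d -> %d species", scen$scenarios$gap_rank,
                                  scen$scenarios$n_species), collapse = "; "))
  })

  # -- tree ------------------------------------------------------------------
  run_stage("tree", {
    tree_dm <- convert_units(main, "fraction")
    tr <- nj_tree(tree_dm)
    ogs <- if (!is.null(md)) md$label[md$group == "outgroup"] else character(0)
    ogs <- intersect(ogs, tr$tip.label)
    rooted <- if (length(ogs)) outgroup_root(tr, ogs) else midpoint_root(tr)
    files$tree <- file.path(config$outdir, "nj_tree.nwk")
    ape::write.tree(rooted, file = files$tree)
    bundle$tree <- rooted
    logf("tree", sprintf("NJ tree, %s-rooted, %d tips",
                         if (length(ogs)) "outgroup" else "midpoint",
                         length(rooted$tip.label)))
  })

  # -- dating ----------------------------------------------------------------
  run_stage("dating", {
    clk <- config$clock
    if (is.null(clk$seed)) clk$seed <- config$seed
    um <- ultrametricize(bundle$tree)
    dated <- clock_dates(um, clk)
    files$dated_tree <- file.path(config$outdir, "dated_tree.nwk")
    files$node_ages <- file.path(config$outdir, "node_ages.tsv")
    write_dated_tree(dated, files$dated_tree, files$node_ages)
    bundle$dated <- dated
    n <- length(dated$tree$tip.label)
    logf("dating", sprintf("root age %.4g Ma", dated$ages[n + 1L]))
  })

  files$log <- file.path(config$outdir, "pipeline.log")
  writeLines(c(paste0("# ", prov), log_lines), files$log)
  bundle$files <- files
  bundle$log <- log_lines
  invisible(bundle)
}
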