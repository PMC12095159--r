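# End-to-end orchestration: simulate -> quantify -> differential screen ->
# classifier bench -> three-class net -> clinical association ->
# cross-reactivity, with one master seed fanned out into per-stage
# substreams and a JSON manifest of parameters, seeds and output hashes.

run_config_defaults <- function() {
  list(
    stages = c("simulate", "quantify", "differential", "bench", "net",
               "clinical", "crossreact"),
    seed = 1L,
    sim = list(),                 # overrides for sim_config()
    p_threshold = 0.05,
    fc_threshold = 2,
    bench_folds = 5L,
    bench_budget = 0L,
    auc_gate = 0.96,
    top_k = 10L,
    min_models = 2L,
    net_folds = 3L,
    net_hidden = c(8L, 4L),
    net_lr = 0.001,
    net_epochs = 150L,
    net_batch = 16L,
    r_threshold = 0.5,
    traits = NULL                 # NULL = every trait column in subjects
  )
}

#' Build a pipeline run configuration
#'
#' Defaults carry the analysis constants the pipeline is built around:
#' p < 0.05 and fold change >= 2 for the screen, ROC-AUC gate 0.96 and
#' top-10 consensus with a 2-model minimum, 5-fold CV for the binary bench,
#' and the 3-fold / 8-4 hidden / lr 0.001 / 150 epochs / batch 16 recipe for
#' the three-class net, with Spearman r > 0.5 for cross-reactivity
#' candidates. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see
#'   `pwabs:::run_config_defaults`).
#' @return A validated `pwabs_run_config` list.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("run_config: unknown keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pwabs_run_config")
}

# per-stage substream: deterministic offset from the master seed, so any
# stage can be re-run in isolation with the same draw
stage_seed <- function(master, stage) {
  offsets <- c(simulate = 101L, quantify = 0L, differential = 0L,
               bench = 301L, net = 401L, clinical = 0L, crossreact = 0L,
               sequences = 501L)
  master + offsets[[stage]]
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort, writes every
#' stage artifact under `outdir`, and records a manifest (JSON) of stage
#' parameters, seeds and output-file MD5 hashes. Identical configuration and
#' seed reproduce byte-identical artifacts and manifest hashes. A stage
#' failure halts the run with the stage name; artifacts already written are
#' retained.
#'
#' @param config A [run_config].
#' @param outdir Output directory (created if needed).
#' @return Invisible list with the in-memory stage results and the manifest.
#' @export
run_all <- function(config = run_config(), outdir = tempfile("pwabs_run_")) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  out <- function(f) file.path(outdir, f)
  files_of <- function(stage) manifest$stages[[stage]]$outputs

  note <- function(stage, params, files) {
    hashes <- as.list(tools::md5sum(unlist(files)))
    names(hashes) <- basename(names(hashes))
    manifest$stages[[stage]] <<- list(
      params = params, seed = stage_seed(config$seed, stage),
      outputs = as.list(unlist(files)), md5 = hashes)
    message("[pwabs] stage ", stage, " complete (seed ",
            stage_seed(config$seed, stage), ")")
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    sim_args <- config$sim
    sim_args$seed <- stage_seed(config$seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    cohort <- generate_cohort(cfg)
    results$cohort <<- cohort
    f1 <- write_fluorescence_tsv(cohort$fluorescence, out("fluorescence.tsv"))
    f2 <- write_subjects_csv(cohort$subjects, out("subjects.csv"))
    f3 <- write_truth_json(cohort$truth, out("truth.json"))
    seqs <- generate_sequences(colnames(cohort$truth$latent_au),
                               seed = stage_seed(config$seed, "sequences"))
    results$sequences <<- seqs
    f4 <- write_fasta(seqs, out("antigens.fasta"))
    note("simulate", list(sim = sim_args), list(f1, f2, f3, f4))
  })

  run_stage("quantify", function() {
    tbl <- read_fluorescence_tsv(out("fluorescence.tsv"))
    aum <- build_au_matrix(tbl)
    results$au <<- aum
    f1 <- write_au_csv(aum, out("au_matrix.csv"), out("sal.csv"))
    note("quantify", list(), list(f1, out("sal.csv")))
  })

  run_stage("differential", function() {
    subjects <- read_subjects_csv(out("subjects.csv"))
    aum <- results$au
    diff <- volcano_select(aum, subjects$diagnosis,
                           p_threshold = config$p_threshold,
                           fc_threshold = config$fc_threshold)
    results$differential <<- diff
    f1 <- write_differential_csv(diff, out("differential.csv"),
                                 out("volcano.csv"), out("selected_antigens.txt"))
    sel <- diff$antigen_id[diff$in_union]
    if (length(sel) >= 1L && nrow(aum$au) >= 2L) {
      emb <- pca_embed(aum$au[, sel, drop = FALSE])
      utils::write.csv(data.frame(subject_id = rownames(emb$scores),
                                  emb$scores), out("pca_scores.csv"),
                       row.names = FALSE)
      results$pca <<- emb
    }
    note("differential",
         list(p_threshold = config$p_threshold,
              fc_threshold = config$fc_threshold),
         list(out("differential.csv"), out("volcano.csv"),
              out("selected_antigens.txt")))
  })

  run_stage("bench", function() {
    subjects <- read_subjects_csv(out("subjects.csv"))
    sel <- readLines(out("selected_antigens.txt"))
    if (length(sel) < 2L)
      stop("fewer than 2 antigens selected; bench needs a feature panel")
    X <- results$au$au[, sel, drop = FALSE]
    y <- binary_labels(subjects$diagnosis, "AD")
    bench <- bench_run(X, y, k = config$bench_folds,
                       seed = stage_seed(config$seed, "bench"),
                       budget = config$bench_budget)
    cons <- consensus_select(bench, auc_gate = config$auc_gate,
                             top_k = config$top_k,
                             min_models = config$min_models)
    results$bench <<- bench
    results$consensus <<- cons
    utils::write.csv(bench$table, out("bench_table.csv"), row.names = FALSE)
    imp <- do.call(cbind, lapply(bench$reports, function(r) r$importance))
    colnames(imp) <- names(bench$reports)
    utils::write.csv(data.frame(antigen_id = rownames(imp), imp,
                                check.names = FALSE),
                     out("importances.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(qualifying = cons$qualifying,
           top_lists = cons$top_lists,
           counts = as.list(cons$counts),
           selected = cons$selected),
      out("consensus.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("bench", list(folds = config$bench_folds, budget = config$bench_budget,
                       auc_gate = config$auc_gate, top_k = config$top_k,
                       min_models = config$min_models),
         list(out("bench_table.csv"), out("importances.csv"),
              out("consensus.json")))
  })

  run_stage("net", function() {
    subjects <- read_subjects_csv(out("subjects.csv"))
    sel <- readLines(out("selected_antigens.txt"))
    X <- results$au$au[, sel, drop = FALSE]
    cfg <- net_config(input_dim = ncol(X), hidden = config$net_hidden,
                      lr = config$net_lr, epochs = config$net_epochs,
                      batch_size = config$net_batch,
                      seed = stage_seed(config$seed, "net"))
    rep <- net_train(X, subjects$diagnosis, cfg, folds = config$net_folds)
    results$net <<- rep
    write_net_report(rep, out("net_loss_curves.csv"), out("net_confusion.csv"),
                     out("net_metrics.json"))
    note("net", list(folds = config$net_folds, hidden = config$net_hidden,
                     lr = config$net_lr, epochs = config$net_epochs,
                     batch = config$net_batch),
         list(out("net_loss_curves.csv"), out("net_confusion.csv"),
              out("net_metrics.json")))
  })

  run_stage("clinical", function() {
    subjects <- read_subjects_csv(out("subjects.csv"))
    feats <- results$consensus$selected
    if (length(feats) == 0L)
      feats <- utils::head(readLines(out("selected_antigens.txt")), 12L)
    traits <- config$traits
    if (is.null(traits))
      traits <- setdiff(names(subjects), c("subject_id", "diagnosis"))
    assoc <- trait_correlations(results$au$au[, feats, drop = FALSE],
                                subjects, traits)
    results$clinical <<- assoc
    write_assoc_csv(assoc, out("assoc_rho.csv"), out("assoc_p.csv"),
                    out("assoc_stars.csv"))
    note("clinical", list(traits = traits, antibodies = feats),
         list(out("assoc_rho.csv"), out("assoc_p.csv"),
              out("assoc_stars.csv")))
  })

  run_stage("crossreact", function() {
    feats <- results$consensus$selected
    if (length(feats) < 2L)
      feats <- utils::head(readLines(out("selected_antigens.txt")), 12L)
    seqs <- if (!is.null(results$sequences)) results$sequences
            else read_fasta(out("antigens.fasta"))
    scr <- crossreact_screen(feats, results$au, seqs,
                             r_threshold = config$r_threshold)
    results$crossreact <<- scr
    write_crossreact(scr, out("crossreact_corr.csv"),
                     out("crossreact_pairs.tsv"))
    note("crossreact", list(r_threshold = config$r_threshold),
         list(out("crossreact_corr.csv"), out("crossreact_pairs.tsv")))
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = manifest_path, outdir = outdir))
}
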