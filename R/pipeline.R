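# End-to-end drivers and the command-line interface.
#
# Every driver validates its configuration up front, seeds all randomness
# explicitly, and embeds the config + seed + package version in its outputs.

pkg_version <- function() {
  as.character(utils::packageVersion("clockshift"))
}

provenance <- function(config, seed) {
  list(package = "clockshift", version = pkg_version(),
       seed = seed, config = config,
       config_hash = digest_config(config))
}

# tiny deterministic config hash (no external digest dependency)
digest_config <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 1e9
}

#' Read and validate a run configuration (YAML)
#'
#' Recognized fields: `focal`, `ref`, `tree`, `labels`, `ncat`, `gap`,
#' `freq_mode`, `fpkm_threshold`, `adjust`, `seed`, `out`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(ncat = 5L, gap = "missing", freq_mode = "F3x4",
                   fpkm_threshold = 1, adjust = "BH", seed = 1L,
                   include_stem = FALSE)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$gap %in% c("missing", "strict")) stop("gap must be missing|strict")
  if (!cfg$freq_mode %in% c("F3x4", "equal"))
    stop("freq_mode must be F3x4|equal")
  cfg
}

load_labelled_tree <- function(tree_path, labels_path = NULL) {
  tree <- parse_newick(paste(readLines(tree_path), collapse = ""))
  if (!is.null(labels_path))
    tree <- label_branches(tree, read_branch_labels(labels_path))
  tree
}

#' Acceleration-test driver: files in, JSON + text report out
#'
#' @param config list (or path to YAML) with `focal`, `ref`, `tree`,
#'   optional `labels`, `ncat`, `gap`, `seed`, `out`.
#' @return the `acceleration_result`, invisibly.
#' @export
cmd_accel <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (f in c("focal", "ref", "tree", "out")) {
    if (is.null(config[[f]]))
      stop(sprintf("missing required config field '%s'", f))
  }
  for (f in c("focal", "ref", "tree"))
    if (!file.exists(config[[f]]))
      stop(sprintf("config field '%s': file not found: %s", f, config[[f]]))
  tree <- load_labelled_tree(config$tree, config$labels)
  focal <- read_alignment(config$focal, guess_format(config$focal))
  ref <- read_alignment(config$ref, guess_format(config$ref))
  res <- run_acceleration_test(focal, ref, tree, ncat = config$ncat,
                               gap = config$gap, restarts = 1L,
                               seed = config$seed)
  # provenance omits the output path so identical runs give identical bytes
  cfg_rec <- config[setdiff(names(config), "out")]
  write_acceleration_report(res, config$out,
                            config = provenance(cfg_rec, config$seed))
  txt <- sub("\\.json$", ".txt", config$out)
  if (txt == config$out) txt <- paste0(config$out, ".txt")
  utils::capture.output(print(res), file = txt)
  invisible(res)
}

guess_format <- function(path) {
  if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE)) "phylip" else "fasta"
}

#' Simulation driver: writes FASTA + Newick + YAML provenance
#'
#' @param out_prefix output path prefix.
#' @param tree tree (defaults to the bundled primate fixture).
#' @param nsites sites to simulate.
#' @param class_rates per-class rate multipliers.
#' @param kappa,alpha,ncat,pi HKY+gamma parameters.
#' @param seed RNG seed.
#' @export
cmd_simulate <- function(out_prefix, tree = fixture_primate_tree(),
                         nsites = 690L, class_rates = c(1, 1, 1),
                         kappa = 4, alpha = 0.8, ncat = 5L,
                         pi = c(0.3, 0.2, 0.2, 0.3), seed = 1L) {
  model <- hky_params(kappa = kappa, pi = pi, alpha = alpha, ncat = ncat)
  aln <- simulate_alignment(tree, model, nsites, class_rates, seed = seed)
  write_alignment(aln, paste0(out_prefix, ".fa"))
  writeLines(write_newick(tree), paste0(out_prefix, ".nwk"))
  cfg <- list(nsites = nsites, class_rates = class_rates, kappa = kappa,
              alpha = alpha, ncat = ncat, pi = pi)
  yaml::write_yaml(provenance(cfg, seed), paste0(out_prefix, ".yaml"))
  invisible(aln)
}

#' Self-contained demonstration of the whole analysis on synthetic data
#'
#' Simulates a promoter-like and an intron-like alignment and a codon
#' alignment on the bundled primate fixture, plus a binary expression trait
#' on the bundled mammal chronogram, then runs: M0 fit, free-branch fits,
#' local-clock fits, the acceleration test, ancestral reconstruction, Fitch
#' counting, phylogenetic logistic regression, and a small correlation
#' screen.  Writes per-stage outputs and a JSON summary comparing recovered
#' parameters with the simulation truth.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (created).
#' @param promoter_bp,intron_bp,n_codons simulated alignment sizes.
#' @return the summary list, invisibly.
#' @export
run_full_demo <- function(seed = 1L, out_dir = tempfile("clockshift_demo"),
                          promoter_bp = 690L, intron_bp = 4000L,
                          n_codons = 477L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  truth <- list(kappa = 4, alpha = 0.8, pi = c(0.3, 0.2, 0.2, 0.3),
                promoter_rates = c(1, 0.527281, 0.3525),
                intron_rates = c(1, 0.29572, 0.216),
                omega = 0.039)
  tree <- fixture_primate_tree()
  model <- hky_params(kappa = truth$kappa, pi = truth$pi,
                      alpha = truth$alpha, ncat = 5L)

  prom <- stage("simulate promoter", simulate_alignment(
    tree, model, promoter_bp, truth$promoter_rates, seed = seed))
  intr <- stage("simulate introns", simulate_alignment(
    tree, model, intron_bp, truth$intron_rates, seed = seed + 1L))
  write_alignment(prom, file.path(out_dir, "promoter.fa"))
  write_alignment(intr, file.path(out_dir, "introns.fa"))
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))

  cod_model <- m0_params(kappa = truth$kappa, omega = truth$omega,
                         freq_mode = "equal")
  cds <- stage("simulate CDS", simulate_codon_alignment(
    tree, cod_model, n_codons, seed = seed + 2L))
  write_alignment(cds, file.path(out_dir, "cds.fa"))

  m0 <- stage("M0 fit", fit_m0(cds, tree, restarts = 0L, seed = seed))
  m0_se <- parameter_ses(m0, c("kappa", "omega"))

  fb_prom <- stage("free branches (promoter)",
                   fit_free_branches(tree, prom, restarts = 0L, seed = seed))
  accel <- stage("acceleration test", run_acceleration_test(
    prom, intr, tree, restarts = 0L, seed = seed))
  write_acceleration_report(accel, file.path(out_dir, "acceleration.json"),
                            config = provenance(list(seed = seed), seed))

  anc <- stage("ancestral reconstruction", marginal_reconstruction(
    accel$fit_focal$tree, prom,
    hky_params(kappa = accel$fit_focal$kappa, pi = accel$fit_focal$pi,
               alpha = accel$fit_focal$alpha, ncat = 5L)))
  utils::write.table(extract_sites(anc, columns = seq_len(min(25L, promoter_bp))),
                     file.path(out_dir, "ancestral_head.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  mam <- fixture_mammal_tree()
  X <- stage("simulate mammal covariates", {
    set.seed(seed + 3L)
    lhr <- stats::rnorm(n_tips(mam), 2.2, 0.35)  # log10 heart rate, bpm
    cbind(log_heart_rate = lhr)
  })
  yb <- stage("simulate expression states", simulate_binary_trait(
    mam, decay = 0.05, beta = c(-6.5, 3), cbind(1, X), seed = seed + 4L))
  fitch <- stage("Fitch counting", fitch_min_changes(mam, yb))
  plf <- stage("phylogenetic logistic regression",
               phylo_logistic_fit(mam, yb, X))

  expr <- stage("screen matrix", {
    set.seed(seed + 5L)
    g <- matrix(stats::rnorm(200 * n_tips(mam)), 200,
                dimnames = list(sprintf("gene%03d", 1:200), mam$tip.label))
    g["gene001", ] <- 0.8 * scale(X[, 1])[, 1] +
      sqrt(1 - 0.64) * stats::rnorm(n_tips(mam))
    g
  })
  scr <- stage("correlation screen", correlation_screen(
    expr, stats::setNames(10^X[, 1], mam$tip.label)))
  utils::write.table(utils::head(scr, 20), file.path(out_dir, "screen_top.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  summary <- list(
    provenance = provenance(list(promoter_bp = promoter_bp,
                                 intron_bp = intron_bp,
                                 n_codons = n_codons), seed),
    truth = truth,
    m0 = list(kappa = m0$kappa, omega = m0$omega,
              se = as.list(m0_se$se), lnL = m0$lnL),
    free_branch_promoter = list(lnL = fb_prom$lnL, kappa = fb_prom$kappa,
                                alpha = fb_prom$alpha),
    acceleration = list(
      r1_promoter = accel$r1_focal, r1_intron = accel$r1_ref,
      ratio = accel$ratio, se_ratio = accel$se_ratio,
      percent_excess = accel$percent_excess,
      p_paper = accel$p_paper, p_standard = accel$p_standard,
      promoter_rates = accel$fit_focal$rates,
      intron_rates = accel$fit_ref$rates),
    fitch_changes = fitch$changes,
    phylo_logistic = list(coef = as.list(plf$coef), se = as.list(plf$se),
                          decay = plf$decay, separation = plf$separation),
    screen_top_gene = scr$gene[1])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# ---- command-line interface -------------------------------------------

#' CLI entry point (used by the `clockshift` script in `inst/cli/`)
#'
#' Subcommands: `simulate`, `dnds`, `fit-clock`, `accel`, `ancestral`,
#' `fitch`, `phyloglm`, `screen`, `full-demo`.  Run with no arguments for
#' usage.  Returns an exit code.
#' @param argv character vector of command-line arguments.
#' @export
clockshift_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: clockshift <command> [options]",
    "commands:",
    "  simulate   --out PREFIX [--nsites N] [--seed S] [--tree FILE]",
    "  dnds       --cds FILE --tree FILE [--out FILE]",
    "  fit-branches --aln FILE --tree FILE [--out FILE]",
    "  fit-clock  --aln FILE --tree FILE [--labels FILE] [--out FILE]",
    "  accel      --config FILE | --focal F --ref R --tree T --out O",
    "  ancestral  --aln FILE --tree FILE --out PREFIX",
    "  fitch      --tree FILE --traits TSV [--threshold X]",
    "  phyloglm   --tree FILE --traits TSV [--threshold X]",
    "  screen     --expr TSV --traits TSV --trait-col NAME [--out FILE]",
    "  full-demo  --out DIR [--seed S]",
    sep = "\n")
  if (length(argv) == 0L) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  need <- function(...) {
    for (f in c(...)) if (is.null(opts[[f]]))
      stop(sprintf("command '%s' requires --%s", cmd, f))
  }
  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        need("out")
        tree <- if (is.null(opts$tree)) fixture_primate_tree() else
          load_labelled_tree(opts$tree)
        cmd_simulate(opts$out, tree = tree,
                     nsites = as.integer(opts$nsites %||% 690L),
                     seed = as.integer(opts$seed %||% 1L))
      },
      "dnds" = {
        need("cds", "tree")
        aln <- read_alignment(opts$cds, guess_format(opts$cds), "codon")
        tree <- load_labelled_tree(opts$tree)
        fit <- fit_m0(aln, tree, seed = as.integer(opts$seed %||% 1L))
        se <- parameter_ses(fit, c("kappa", "omega"))
        out <- list(kappa = fit$kappa, omega = fit$omega,
                    se = as.list(se$se), lnL = fit$lnL,
                    converged = fit$converged)
        if (!is.null(opts$out))
          jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA)
        cat(sprintf("omega = %.4f (SE %.4f), kappa = %.3f, lnL = %.3f\n",
                    fit$omega, se$se[["omega"]], fit$kappa, fit$lnL))
      },
      "fit-branches" = {
        need("aln", "tree")
        aln <- read_alignment(opts$aln, guess_format(opts$aln))
        tree <- load_labelled_tree(opts$tree)
        fit <- fit_free_branches(tree, aln,
                                 seed = as.integer(opts$seed %||% 1L))
        cat(sprintf("lnL = %.4f, kappa = %.4f, alpha = %s\n", fit$lnL,
                    fit$kappa, format(fit$alpha, digits = 4)))
        if (!is.null(opts$out))
          writeLines(write_newick(fit$tree), opts$out)
      },
      "fit-clock" = {
        need("aln", "tree")
        aln <- read_alignment(opts$aln, guess_format(opts$aln))
        tree <- load_labelled_tree(opts$tree, opts$labels)
        fit <- fit_local_clock(tree, aln, seed = as.integer(opts$seed %||% 1L))
        cat("rate multipliers:", paste(signif(fit$rates, 6), collapse = " "),
            "\nlnL:", fit$lnL, "\n")
        if (!is.null(opts$out))
          jsonlite::write_json(list(rates = fit$rates, kappa = fit$kappa,
                                    alpha = fit$alpha, lnL = fit$lnL),
                               opts$out, auto_unbox = TRUE, digits = NA)
      },
      "accel" = {
        cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else {
          need("focal", "ref", "tree", "out")
          c(opts, read_run_config_defaults())
        }
        res <- cmd_accel(cfg)
        print(res)
      },
      "ancestral" = {
        need("aln", "tree", "out")
        aln <- read_alignment(opts$aln, guess_format(opts$aln))
        tree <- load_labelled_tree(opts$tree, opts$labels)
        fit <- fit_local_clock(tree, aln, seed = as.integer(opts$seed %||% 1L))
        post <- marginal_reconstruction(
          fit$tree, aln, hky_params(kappa = fit$kappa, pi = fit$pi,
                                    alpha = fit$alpha))
        utils::write.table(extract_sites(post), paste0(opts$out, ".tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        write_ancestral_fasta(post, paste0(opts$out, ".fa"))
      },
      "fitch" = {
        need("tree", "traits")
        tree <- load_labelled_tree(opts$tree)
        tab <- read_trait_table(opts$traits)
        y <- binarize_expression(tab, as.numeric(opts$threshold %||% 1))
        res <- fitch_min_changes(tree, y)
        cat(sprintf("minimum state changes: %d\n", res$changes))
      },
      "phyloglm" = {
        need("tree", "traits")
        tree <- load_labelled_tree(opts$tree)
        tab <- read_trait_table(opts$traits)
        y <- binarize_expression(tab, as.numeric(opts$threshold %||% 1))
        covars <- intersect(c("body_mass_g", "heart_rate_bpm", "bmr"),
                            names(tab))
        X <- log10(as.matrix(tab[match(names(y), tab$species), covars]))
        rownames(X) <- names(y)
        print(phylo_logistic_fit(tree, y, X))
      },
      "screen" = {
        need("expr", "traits")
        col <- opts[["trait-col"]] %||% "heart_rate_bpm"
        expr <- as.matrix(utils::read.delim(opts$expr, row.names = 1L,
                                            check.names = FALSE))
        tab <- read_trait_table(opts$traits)
        trait <- stats::setNames(tab[[col]], tab$species)
        scr <- correlation_screen(expr, trait)
        print(utils::head(scr, 10))
        if (!is.null(opts$out))
          utils::write.table(scr, opts$out, sep = "\t", row.names = FALSE,
                             quote = FALSE)
      },
      "full-demo" = {
        need("out")
        run_full_demo(seed = as.integer(opts$seed %||% 1L),
                      out_dir = opts$out)
      },
      { cat(usage, "\n"); return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_run_config_defaults <- function() {
  list(ncat = 5L, gap = "missing", freq_mode = "F3x4", seed = 1L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
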