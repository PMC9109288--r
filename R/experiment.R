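#' Experimental design of the admixture experiment
#'
#' Describes which parental replicates are simulated, which ordered
#' (immigrant, recipient) mixtures are set up, how many mixture replicates
#' each gets, and at which generations populations are Pool-Seq sampled.
#' The default reproduces the study design: 4 parental replicates sampled
#' at generations 0/110/120/130, 4 ordered pairwise combinations (both
#' orderings of two population pairs), 3 mixture replicates per combination
#' sampled at F1/F20/F29.
#'
#' @param n_parents number of parental replicate populations.
#' @param pairs list of length-2 integer vectors `c(immigrant, recipient)`.
#' @param n_mix_reps mixture replicates per pair.
#' @param parental_timepoints generations at which parents are sampled;
#'   must include 0 and the adaptation endpoint.
#' @param mixed_timepoints post-mixture generations at which mixtures are
#'   sampled (F-labels).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_parents = 4,
                              pairs = list(c(1, 2), c(2, 1), c(3, 4), c(4, 3)),
                              n_mix_reps = 3,
                              parental_timepoints = c(0, 110, 120, 130),
                              mixed_timepoints = c(1, 20, 29)) {
  stopifnot(n_parents >= 1, length(pairs) >= 1, n_mix_reps >= 1)
  for (p in pairs) {
    if (length(p) != 2 || p[1] == p[2]) {
      stop("each pair must name two distinct replicates")
    }
    if (any(p < 1) || any(p > n_parents)) {
      stop(sprintf("pair (%d, %d) references an unknown replicate",
                   p[1], p[2]))
    }
  }
  structure(list(n_parents = as.integer(n_parents), pairs = pairs,
                 n_mix_reps = as.integer(n_mix_reps),
                 parental_timepoints = sort(unique(as.integer(parental_timepoints))),
                 mixed_timepoints = sort(unique(as.integer(mixed_timepoints)))),
            class = "experiment_design")
}

pair_label <- function(p) sprintf("P%d>P%d", p[1], p[2])

#' Simulate the full two-phase admixture experiment
#'
#' Simulates `n_parents` parental replicates from a shared founder
#' population (each with its own deterministic RNG stream derived from the
#' master seed), evolving `adapt_generations` toward the new optimum and
#' continuing to the latest parental timepoint under identical dynamics.
#' At the adaptation endpoint each designed ordered mixture is founded in
#' `n_mix_reps` independent replicates at immigrant fraction `m` and
#' evolved for the mixture phase. All sampled timepoints are Pool-Seq
#' sampled under the given noise model. The run is fully reproducible from
#' the master seed, and per-replicate streams are independent: adding a
#' replicate or pair never perturbs the others.
#'
#' @param cfg a [sim_config()].
#' @param psc a [poolseq_config()].
#' @param design an [experiment_design()].
#' @param seed master seed (default `cfg$seed`).
#' @param sel_threshold true frequency change above which a locus is marked
#'   as selected in a replicate's truth table (default 0.3).
#' @return An object of class `experiment_dataset`: a list with
#'   `parents` (per replicate: `count`, `depth`, `freq`, `true_freq`
#'   matrices, loci x timepoints), `mixed` (per pair and mixture replicate:
#'   the same matrices over F-timepoints plus pair metadata), `truth`
#'   (per-locus data.frame with base encoding, effect and cost sizes,
#'   per-replicate true frequency change and selected flag), and the
#'   configuration (`cfg`, `psc`, `design`, `seed`).
#' @export
run_experiment <- function(cfg, psc = poolseq_config(),
                           design = experiment_design(),
                           seed = cfg$seed, sel_threshold = 0.3) {
  if (is.null(seed)) stop("a master seed is required (cfg$seed or seed =)")
  if (!(0 %in% design$parental_timepoints) ||
      !(cfg$adapt_generations %in% design$parental_timepoints)) {
    stop("parental timepoints must include 0 and the adaptation endpoint")
  }
  if (max(design$mixed_timepoints) > cfg$mix_generations) {
    stop("mixed timepoints exceed mix_generations")
  }
  l <- cfg$n_loci
  t_adapt <- cfg$adapt_generations
  t_max <- max(design$parental_timepoints)

  set.seed(derive_seed(seed, "founder"))
  founder <- founder_population(cfg)

  tp_names <- paste0("g", design$parental_timepoints)
  parents <- vector("list", design$n_parents)
  states110 <- vector("list", design$n_parents)
  dp_true <- matrix(NA_real_, l, design$n_parents)
  for (r in seq_len(design$n_parents)) {
    set.seed(derive_seed(seed, "parent", r))
    pop <- founder
    count <- depth <- true_freq <- matrix(
      NA_real_, l, length(design$parental_timepoints),
      dimnames = list(NULL, tp_names))
    take <- function(gen) {
      j <- match(gen, design$parental_timepoints)
      if (!is.na(j)) {
        ps <- pool_seq_sample(pop, psc)
        count[, j] <<- ps[, "beneficial"]
        depth[, j] <<- rowSums(ps)
        true_freq[, j] <<- allele_freqs(pop)
      }
    }
    take(0)
    for (t in seq_len(t_max)) {
      pop <- advance_generation(pop, cfg, cfg$optimum_new)
      if (t == t_adapt) states110[[r]] <- pop
      take(t)
    }
    dp_true[, r] <- true_freq[, match(t_adapt, design$parental_timepoints)] -
      true_freq[, 1]
    parents[[r]] <- list(count = count, depth = depth,
                         freq = ifelse(depth > 0, count / depth, NA_real_),
                         true_freq = true_freq)
  }

  mtp_names <- paste0("F", design$mixed_timepoints)
  mixed <- list()
  for (p in design$pairs) {
    for (k in seq_len(design$n_mix_reps)) {
      set.seed(derive_seed(seed, "mix", p[1], p[2], k))
      pop <- admix(states110[[p[1]]], states110[[p[2]]],
                   m = cfg$mix_proportion, n = cfg$census_size)
      count <- depth <- true_freq <- matrix(
        NA_real_, l, length(design$mixed_timepoints),
        dimnames = list(NULL, mtp_names))
      for (t in seq_len(max(design$mixed_timepoints))) {
        pop <- advance_generation(pop, cfg, cfg$optimum_new)
        j <- match(t, design$mixed_timepoints)
        if (!is.na(j)) {
          ps <- pool_seq_sample(pop, psc)
          count[, j] <- ps[, "beneficial"]
          depth[, j] <- rowSums(ps)
          true_freq[, j] <- allele_freqs(pop)
        }
      }
      mixed[[sprintf("%s.r%d", pair_label(p), k)]] <-
        list(immigrant = p[1], recipient = p[2], mix_rep = k,
             count = count, depth = depth,
             freq = ifelse(depth > 0, count / depth, NA_real_),
             true_freq = true_freq)
    }
  }

  set.seed(derive_seed(seed, "bases"))
  bases <- c("A", "T", "C", "G")
  ref <- sample(bases, l, replace = TRUE)
  beneficial <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  truth <- data.frame(
    locus = seq_len(l), chrom = "sim1", pos = 1000L * seq_len(l),
    ref_base = ref, beneficial_base = unname(beneficial),
    a = cfg$effect_sizes, c = cfg$cost_per_locus,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(design$n_parents)) {
    truth[[sprintf("dp_P%d", r)]] <- dp_true[, r]
    truth[[sprintf("selected_P%d", r)]] <- dp_true[, r] > sel_threshold
  }

  structure(list(parents = parents, mixed = mixed, truth = truth,
                 cfg = cfg, psc = psc, design = design, seed = seed),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf(paste0("experiment_dataset: %d loci, %d parental replicates, ",
                     "%d mixed populations (seed %d)\n"),
              x$cfg$n_loci, length(x$parents), length(x$mixed), x$seed))
  invisible(x)
}

# 32-bit FNV-1a over a deparsed object; stable config fingerprint.
config_hash <- function(...) {
  txt <- paste(deparse(list(...)), collapse = "")
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

dataset_sample_table <- function(ds) {
  tabs <- list()
  for (r in seq_along(ds$parents)) {
    tabs[[length(tabs) + 1]] <- data.frame(
      sample = paste0("P", r, "_", colnames(ds$parents[[r]]$count)),
      type = "parental", population = paste0("P", r),
      immigrant = NA_integer_, recipient = NA_integer_,
      mix_rep = NA_integer_,
      generation = ds$design$parental_timepoints,
      stringsAsFactors = FALSE)
  }
  for (nm in names(ds$mixed)) {
    mx <- ds$mixed[[nm]]
    tabs[[length(tabs) + 1]] <- data.frame(
      sample = paste0(gsub(">", "v", nm), "_", colnames(mx$count)),
      type = "mixed", population = nm,
      immigrant = mx$immigrant, recipient = mx$recipient,
      mix_rep = mx$mix_rep,
      generation = ds$design$mixed_timepoints,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  tab$column <- seq_len(nrow(tab))
  tab
}

dataset_as_sync <- function(ds) {
  tab <- dataset_sample_table(ds)
  l <- ds$cfg$n_loci
  counts <- array(0L, dim = c(l, nrow(tab), 6),
                  dimnames = list(NULL, tab$sample, SYNC_BASES))
  slot <- function(pop, tp) {
    list(beneficial = pop$count[, tp], depth = pop$depth[, tp])
  }
  for (i in seq_len(nrow(tab))) {
    src <- if (tab$type[i] == "parental") {
      ds$parents[[as.integer(sub("P", "", tab$population[i]))]]
    } else {
      ds$mixed[[tab$population[i]]]
    }
    tp <- sub(".*_", "", tab$sample[i])
    s <- slot(src, tp)
    ib <- match(ds$truth$beneficial_base, SYNC_BASES)
    ir <- match(ds$truth$ref_base, SYNC_BASES)
    counts[cbind(seq_len(l), i, ib)] <- as.integer(s$beneficial)
    counts[cbind(seq_len(l), i, ir)] <- as.integer(s$depth - s$beneficial)
  }
  structure(list(info = data.frame(chrom = ds$truth$chrom,
                                   pos = ds$truth$pos,
                                   ref = ds$truth$ref_base,
                                   stringsAsFactors = FALSE),
                 counts = counts),
            class = "sync")
}

#' Write an experiment dataset as sync, truth, and manifest files
#'
#' Emits `experiment.sync` (one column per sampled population-timepoint),
#' `truth.tsv` (per-locus base encoding, effects, costs, and per-replicate
#' selected flags), `manifest.tsv` (sample-to-column map with population,
#' type, and generation), and `run_info.tsv` (master seed and configuration
#' hash). Rerunning with the same dataset is byte-identical.
#'
#' @param ds an [run_experiment()] result.
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment_files <- function(ds, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory is not empty; use force = TRUE to overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sync = file.path(dir, "experiment.sync"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             run_info = file.path(dir, "run_info.tsv"))
  write_sync(dataset_as_sync(ds), paths["sync"])
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset_sample_table(ds), paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  info <- data.frame(key = c("seed", "config_hash"),
                     value = c(ds$seed,
                               config_hash(ds$cfg, ds$psc, ds$design)),
                     stringsAsFactors = FALSE)
  utils::write.table(info, paths["run_info"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Rebuild beneficial-allele count matrices from written experiment files
#'
#' Reads `experiment.sync`, `manifest.tsv`, and `truth.tsv` back into the
#' matrix bundle consumed by [analyze_experiment()], tracking each locus'
#' beneficial base as recorded in the truth table.
#'
#' @param dir directory written by [write_experiment_files()].
#' @return A list with `parents`, `mixed`, `truth`, `design`-like fields
#'   mirroring an [run_experiment()] dataset (without true frequencies).
#' @export
read_experiment_files <- function(dir) {
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  sync <- read_sync(file.path(dir, "experiment.sync"),
                    sample_names = manifest$sample)
  fq <- frequencies(sync, truth$beneficial_base)
  cnt <- round(fq$freq * fq$depth)
  parents <- list()
  mixed <- list()
  for (popname in unique(manifest$population)) {
    rows <- manifest[manifest$population == popname, ]
    cols <- rows$column
    tp <- if (rows$type[1] == "parental") paste0("g", rows$generation) else
      paste0("F", rows$generation)
    pick <- function(m) {
      m <- m[, cols, drop = FALSE]
      colnames(m) <- tp
      m
    }
    entry <- list(count = pick(cnt), depth = pick(fq$depth),
                  freq = pick(fq$freq))
    if (rows$type[1] == "parental") {
      parents[[as.integer(sub("P", "", popname))]] <- entry
    } else {
      entry$immigrant <- rows$immigrant[1]
      entry$recipient <- rows$recipient[1]
      entry$mix_rep <- rows$mix_rep[1]
      mixed[[popname]] <- entry
    }
  }
  list(parents = parents, mixed = mixed, truth = truth, manifest = manifest)
}
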