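#' Simulation settings for synthetic banks and patient pairs
#'
#' Bundles the knobs of the synthetic-data generator. Defaults describe a
#' desk-scale study: 2000 genes, a bank of 50 perturbation instances, 100
#' pathways of 10-80 genes, 50 up- plus 50 down-signature genes per
#' instance concentrated in 5 affected pathways, a 2 log2-unit planted
#' effect and 0.5 log2 units of Gaussian noise.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_instances Number of bank instances.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Integer pair: min/max pathway size.
#' @param signature_size Signature genes per direction (up and down).
#' @param affected_pathways_per_instance Pathways carrying each instance's
#'   signature.
#' @param effect_size Planted effect in log2 units.
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param baseline_mean,baseline_sd Per-gene baseline intensity
#'   distribution (log2 scale) for patient pairs.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000, n_instances = 50,
                              n_pathways = 100,
                              pathway_size_range = c(10, 80),
                              signature_size = 50,
                              affected_pathways_per_instance = 5,
                              effect_size = 2.0, noise_sd = 0.5,
                              baseline_mean = 8, baseline_sd = 1,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_instances = as.integer(n_instances),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              signature_size = as.integer(signature_size),
              affected_pathways_per_instance =
                as.integer(affected_pathways_per_instance),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_instances > 0, n_pathways > 0,
              length(pathway_size_range) == 2,
              pathway_size_range[1] >= 1,
              pathway_size_range[2] >= pathway_size_range[1],
              pathway_size_range[2] <= n_genes,
              signature_size >= 1,
              affected_pathways_per_instance >= 1,
              affected_pathways_per_instance <= n_pathways,
              effect_size >= 0, noise_sd >= 0, baseline_sd >= 0)
    if (signature_size > n_genes / 4)
      stop("`signature_size` must be <= n_genes / 4")
  })
  structure(cfg, class = "simulation_config")
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a pathway collection
#'
#' Draws `n_pathways` gene sets with sizes uniform over
#' `pathway_size_range`, sampled without replacement within a pathway;
#' overlap between pathways is allowed.
#'
#' @param cfg A [simulation_config()]. The caller controls the RNG state
#'   (see [simulate_bank()]).
#' @return A [pathway_collection()].
#' @export
simulate_pathways <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  genes <- .gene_ids(cfg$n_genes)
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("pw%03d", seq_len(cfg$n_pathways))
  pathway_collection(sets, descriptions = paste("simulated pathway, size", sizes))
}

#' Simulate a reference bank with planted drug signatures
#'
#' Each instance receives disjoint up and down signature gene sets sampled
#' from the union of its affected pathways (the affected set is redrawn, up
#' to 100 attempts, until that union can hold the signature; an error is
#' raised only when the configuration cannot be satisfied). The instance's
#' ranked profile orders genes by a latent effect vector — `+effect_size`
#' on up genes, `-effect_size` on down genes, 0 elsewhere — plus Gaussian
#' noise of SD `noise_sd`. With `noise_sd = 0` every up gene outranks every
#' null gene. The returned truth table records each instance's planted
#' signature and affected pathways.
#'
#' @param cfg A [simulation_config()]; `cfg$seed` initializes the RNG for
#'   the pathways, the bank and the truth table together.
#' @return A list with elements `bank` (a [reference_bank()]), `pathways`
#'   (a [pathway_collection()]) and `truth` (a list per instance with
#'   `up`, `down`, `affected_pathways`).
#' @export
simulate_bank <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- .gene_ids(cfg$n_genes)
  pathways <- simulate_pathways(cfg)
  need <- 2L * cfg$signature_size
  max_union <- length(unique(unlist(
    pathways[order(lengths(pathways), decreasing = TRUE)[
      seq_len(cfg$affected_pathways_per_instance)]])))
  if (need > max_union)
    stop("signature (", need, " genes) cannot fit in the union of ",
         cfg$affected_pathways_per_instance, " affected pathways (at most ",
         max_union, " genes)")

  ids <- sprintf("inst%03d", seq_len(cfg$n_instances))
  compounds <- sprintf("compound_%02d", seq_len(cfg$n_instances))
  doses <- sample(c("100 nM", "1 uM", "10 uM", "100 uM"),
                  cfg$n_instances, replace = TRUE)
  ranks <- matrix(NA_integer_, cfg$n_genes, cfg$n_instances,
                  dimnames = list(genes, ids))
  truth <- vector("list", cfg$n_instances)
  names(truth) <- ids
  for (i in seq_len(cfg$n_instances)) {
    for (try in seq_len(100)) {
      affected <- sample(names(pathways), cfg$affected_pathways_per_instance)
      pool <- unique(unlist(unclass(pathways)[affected], use.names = FALSE))
      if (length(pool) >= need) break
      affected <- NULL
    }
    if (is.null(affected))
      stop("could not draw an affected-pathway union large enough for the ",
           "signature of instance ", ids[[i]])
    sig_genes <- sample(pool, need)
    up <- sig_genes[seq_len(cfg$signature_size)]
    down <- sig_genes[-seq_len(cfg$signature_size)]
    effect <- numeric(cfg$n_genes)
    names(effect) <- genes
    effect[up] <- cfg$effect_size
    effect[down] <- -cfg$effect_size
    latent <- effect + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
    # rank 1 = most up-regulated; ties (noise_sd = 0) broken by gene id
    o <- order(-latent, genes)
    r <- integer(cfg$n_genes)
    r[o] <- seq_len(cfg$n_genes)
    ranks[, i] <- r
    truth[[i]] <- list(up = up, down = down, affected_pathways = affected)
  }
  meta <- data.frame(instance_id = ids, compound = compounds, dose = doses,
                     cell_line = "synthetic", stringsAsFactors = FALSE)
  list(bank = reference_bank(meta, ranks), pathways = pathways, truth = truth)
}

#' Simulate a paired pre/post patient profile with a planted instance effect
#'
#' The pre column is a per-gene baseline drawn from
#' Normal(`baseline_mean`, `baseline_sd`) on the log2 scale; the post
#' column adds `+effect_size` on the instance's planted up genes and
#' `-effect_size` on its down genes (signs flipped when `reverse = TRUE`)
#' plus Gaussian noise of SD `noise_sd`, emulating a treatment whose
#' expression effect mimics (or reverses) that reference perturbation.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth table from [simulate_bank()].
#' @param mimic_instance Instance id whose signature the patient carries.
#' @param reverse Flip the planted signs.
#' @param patient Patient identifier used in the pairing table.
#' @param seed Seed for the patient-level randomness (default derived from
#'   `cfg$seed`).
#' @return An [expression_matrix()] with two columns and one pairing entry.
#' @export
simulate_patient_pair <- function(cfg, truth, mimic_instance,
                                  reverse = FALSE, patient = "P1",
                                  seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!mimic_instance %in% names(truth))
    stop("unknown instance: ", mimic_instance)
  set.seed(seed)
  genes <- .gene_ids(cfg$n_genes)
  tr <- truth[[mimic_instance]]
  effect <- numeric(cfg$n_genes)
  names(effect) <- genes
  s <- if (reverse) -1 else 1
  effect[tr$up] <- s * cfg$effect_size
  effect[tr$down] <- -s * cfg$effect_size
  pre <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  post <- pre + effect + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
  v <- cbind(pre, post)
  dimnames(v) <- list(genes, paste0(patient, c("_pre", "_post")))
  expression_matrix(v, pairs = data.frame(patient = patient,
                                          pre = colnames(v)[1],
                                          post = colnames(v)[2],
                                          stringsAsFactors = FALSE))
}

#' Write a complete synthetic scenario to disk
#'
#' Materializes a simulated bank, pathway collection, patient pair and
#' truth table in the package's file dialects (bank directory, GMT,
#' expression TSV, truth CSV), ready to be consumed by [run_pbsc()].
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory.
#' @param mimic_instance Instance the patient pair mimics (default the
#'   first).
#' @param reverse Flip the planted patient effect.
#' @return Invisibly, the simulated objects as from [simulate_bank()] plus
#'   `patient` (the [expression_matrix()]).
#' @export
write_simulation <- function(cfg, dir, mimic_instance = NULL,
                             reverse = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_bank(cfg)
  if (is.null(mimic_instance)) mimic_instance <- names(sim$truth)[[1]]
  pat <- simulate_patient_pair(cfg, sim$truth, mimic_instance,
                               reverse = reverse)
  write_reference_bank(sim$bank, file.path(dir, "bank"))
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  write_expression_matrix(pat, file.path(dir, "expression.tsv"))
  truth_df <- do.call(rbind, lapply(names(sim$truth), function(id) {
    tr <- sim$truth[[id]]
    data.frame(instance_id = id,
               up_genes = paste(tr$up, collapse = ";"),
               down_genes = paste(tr$down, collapse = ";"),
               affected_pathways = paste(tr$affected_pathways, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(c(sim, list(patient = pat, mimic_instance = mimic_instance)))
}
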