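#' Platform descriptor for the synthetic generator
#'
#' Describes how a platform realizes probes from the shared gene-symbol
#' universe: a fraction of genes is absent (dropout), a fraction carries
#' several distinct probes (multi-probe genes), and — on GEH-like platforms
#' only — a fraction of probe IDs is emitted twice, which downstream
#' preprocessing must average away.
#'
#' @param name platform label, e.g. `"AFX"` or `"GEH"`.
#' @param dropout_rate fraction of universe genes absent from the platform.
#' @param multi_probe_rate fraction of measured genes represented by 2-3
#'   distinct probes rather than one.
#' @param duplicate_id_rate fraction of probes whose ID appears twice in the
#'   emitted matrix (independent measurements sharing one ID).
#' @return a `platform_spec` list.
#' @export
platform_spec <- function(name, dropout_rate = 0.05, multi_probe_rate = 0.1,
                          duplicate_id_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("platform name must be a non-empty string")
  for (r in c(dropout_rate, multi_probe_rate, duplicate_id_rate))
    assert_scalar_number(r, "platform rate", min = 0, max = 1)
  structure(list(name = name, dropout_rate = dropout_rate,
                 multi_probe_rate = multi_probe_rate,
                 duplicate_id_rate = duplicate_id_rate),
            class = "platform_spec")
}

default_platforms <- function() {
  list(platform_spec("AFX", dropout_rate = 0.05, multi_probe_rate = 0.10,
                     duplicate_id_rate = 0),
       platform_spec("GEH", dropout_rate = 0.10, multi_probe_rate = 0.05,
                     duplicate_id_rate = 0.02))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic MAQC-like world: a universe of gene
#' symbols with baseline log2 means, a designated DEG subset with sampled
#' log2 effects between reference samples A and B, the titration mixtures
#' C = 0.75A + 0.25B and D = 0.25A + 0.75B built on the natural scale,
#' replicated measurements at several test sites per platform with additive
#' per-probe site offsets and intensity-dependent replicate noise, a
#' low-noise RT-PCR-like assay on a gene subset, and a gene-set collection
#' with a configurable enriched fraction.
#'
#' @param n_genes number of gene symbols in the universe.
#' @param n_deg number of truly differential genes (A versus B).
#' @param effect_size mean absolute log2 difference between A and B over the
#'   DEG subset. Magnitudes are sampled as
#'   `effect_size * (0.6 + Exp(mean 0.4))`, giving mean `effect_size`, sd
#'   `0.4 * effect_size`, and a hard lower bound of `0.6 * effect_size`.
#' @param base_mean_range interval of baseline log2 means for sample A.
#' @param noise_sd replicate noise sd at the brightest genes (log2 units).
#' @param intensity_noise_slope added noise sd per log2 unit below the
#'   brightest baseline mean; makes dim genes noisier, the regime in which
#'   intensity weighting (WAD) and intensity-dependent moderation (ibmT)
#'   earn their keep.
#' @param site_sd sd of additive per-probe site offsets (log2 units).
#' @param n_sites test sites per platform.
#' @param n_reps replicates per sample type per site (the titration design
#'   uses 5).
#' @param platforms list of [platform_spec()] descriptors.
#' @param rtpcr_n_genes size of the RT-PCR-assayed gene subset.
#' @param rtpcr_n_reps replicates per sample type in the RT-PCR assay.
#' @param rtpcr_noise_sd RT-PCR replicate noise sd; must not exceed
#'   `noise_sd` (the reference assay is the quieter one).
#' @param rtpcr_deg_fraction fraction of assayed genes drawn from the true
#'   DEG subset (capped by availability).
#' @param n_sets number of gene sets in the synthetic collection.
#' @param set_size_range inclusive interval of gene-set sizes.
#' @param enriched_fraction fraction of sets that over-sample DEG genes.
#' @param seed master RNG seed; all per-platform/site streams derive from it.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 1000L, n_deg = 100L, effect_size = 2,
                       base_mean_range = c(4, 14), noise_sd = 0.5,
                       intensity_noise_slope = 0.02, site_sd = 0.2,
                       n_sites = 3L, n_reps = 5L,
                       platforms = default_platforms(),
                       rtpcr_n_genes = 200L, rtpcr_n_reps = 4L,
                       rtpcr_noise_sd = 0.25, rtpcr_deg_fraction = 0.5,
                       n_sets = 186L, set_size_range = c(10L, 60L),
                       enriched_fraction = 0.2, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1)
  n_deg <- assert_count(n_deg, "n_deg", min = 0)
  if (n_deg > n_genes) stop_config("n_deg must not exceed n_genes")
  assert_scalar_number(effect_size, "effect_size", min = 0)
  if (!is.numeric(base_mean_range) || length(base_mean_range) != 2L ||
      base_mean_range[1] > base_mean_range[2])
    stop_config("base_mean_range must be a nondecreasing interval")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(intensity_noise_slope, "intensity_noise_slope", min = 0)
  assert_scalar_number(site_sd, "site_sd", min = 0)
  n_sites <- assert_count(n_sites, "n_sites", min = 1)
  n_reps <- assert_count(n_reps, "n_reps", min = 2)
  if (!is.list(platforms) || !length(platforms) ||
      !all(vapply(platforms, inherits, logical(1), "platform_spec")))
    stop_config("platforms must be a non-empty list of platform_spec objects")
  pnames <- vapply(platforms, `[[`, character(1), "name")
  if (anyDuplicated(pnames)) stop_config("platform names must be unique")
  rtpcr_n_genes <- assert_count(rtpcr_n_genes, "rtpcr_n_genes", min = 1)
  if (rtpcr_n_genes > n_genes)
    stop_config("rtpcr_n_genes must not exceed n_genes")
  rtpcr_n_reps <- assert_count(rtpcr_n_reps, "rtpcr_n_reps", min = 2)
  assert_scalar_number(rtpcr_noise_sd, "rtpcr_noise_sd", min = 0)
  if (rtpcr_noise_sd > noise_sd)
    stop_config("rtpcr_noise_sd must not exceed noise_sd")
  assert_scalar_number(rtpcr_deg_fraction, "rtpcr_deg_fraction", min = 0, max = 1)
  n_sets <- assert_count(n_sets, "n_sets", min = 1)
  if (!is.numeric(set_size_range) || length(set_size_range) != 2L ||
      set_size_range[1] > set_size_range[2] || set_size_range[1] < 1)
    stop_config("set_size_range must be a nondecreasing interval of counts >= 1")
  if (set_size_range[2] > n_genes)
    stop_config("set_size_range upper bound must not exceed n_genes")
  assert_scalar_number(enriched_fraction, "enriched_fraction", min = 0, max = 1)
  seed <- assert_count(seed, "seed", min = 0)
  structure(list(n_genes = n_genes, n_deg = n_deg, effect_size = effect_size,
                 base_mean_range = as.numeric(base_mean_range),
                 noise_sd = noise_sd,
                 intensity_noise_slope = intensity_noise_slope,
                 site_sd = site_sd, n_sites = n_sites, n_reps = n_reps,
                 platforms = platforms, rtpcr_n_genes = rtpcr_n_genes,
                 rtpcr_n_reps = rtpcr_n_reps, rtpcr_noise_sd = rtpcr_noise_sd,
                 rtpcr_deg_fraction = rtpcr_deg_fraction, n_sets = n_sets,
                 set_size_range = as.integer(round(set_size_range)),
                 enriched_fraction = enriched_fraction, seed = seed),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map one-to-one onto [sim_config()] arguments; platforms are
#' given as a list of mappings with keys name, dropout_rate,
#' multi_probe_rate, duplicate_id_rate.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$platforms)) {
    raw$platforms <- lapply(raw$platforms, function(p) {
      do.call(platform_spec, p)
    })
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_config("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}
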