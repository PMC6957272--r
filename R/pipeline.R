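rck_subcommands <- function() {
  c("ring-metrics", "cluster", "metal-site", "motif", "conserve",
    "flux-fit", "titrate", "simulate-ring", "simulate-site",
    "simulate-alignment", "simulate-trace", "simulate-titration")
}

# effective config = defaults overridden by user values; unknown keys rejected
merge_config <- function(defaults, config) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "rck_usage_error")
  }
  for (k in names(config)) defaults[[k]] <- config[[k]]
  defaults
}

write_report <- function(report, tables, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  for (name in names(tables)) {
    readr::write_tsv(tables[[name]],
                     file.path(out_dir, paste0(stem, "_", name, ".tsv")))
  }
  invisible(NULL)
}

#' Run one pipeline stage with a config, writing machine-readable reports
#'
#' Single orchestration entry point behind the command-line wrapper
#' (`inst/cli/rckring`). Each subcommand runs one analysis or generator
#' stage on file inputs and writes a JSON report (with the effective
#' configuration and package version embedded) plus TSV convenience tables
#' into `out_dir`. Every tunable named in the stage documentation is a
#' config key.
#'
#' @param subcommand One of `"ring-metrics"`, `"cluster"`, `"metal-site"`,
#'   `"motif"`, `"conserve"`, `"flux-fit"`, `"titrate"`, `"simulate-ring"`,
#'   `"simulate-site"`, `"simulate-alignment"`, `"simulate-trace"`,
#'   `"simulate-titration"`.
#' @param config Named list of stage parameters (see Details in the
#'   package vignette); unknown keys are an error.
#' @param out_dir Output directory for reports, or `NULL` to skip writing.
#' @return The report (a named list), invisibly.
#' @export
rck_run <- function(subcommand, config = list(), out_dir = NULL) {
  if (!is.character(subcommand) || length(subcommand) != 1L ||
      !subcommand %in% rck_subcommands()) {
    abort(paste0("unknown subcommand '", paste(subcommand, collapse = ","),
                 "'; expected one of: ",
                 paste(rck_subcommands(), collapse = ", ")),
          class = "rck_usage_error")
  }
  handler <- switch(
    subcommand,
    "ring-metrics" = run_ring_metrics,
    "cluster" = run_cluster,
    "metal-site" = run_metal_site,
    "motif" = run_motif,
    "conserve" = run_conserve,
    "flux-fit" = run_flux_fit,
    "titrate" = run_titrate,
    "simulate-ring" = run_sim_ring,
    "simulate-site" = run_sim_site,
    "simulate-alignment" = run_sim_alignment,
    "simulate-trace" = run_sim_trace,
    "simulate-titration" = run_sim_titration
  )
  res <- handler(config)
  report <- c(
    list(subcommand = subcommand,
         package_version = as.character(utils::packageVersion("rckring")),
         config = res$config),
    res$report
  )
  write_report(report, res$tables, out_dir, gsub("-", "_", subcommand))
  invisible(report)
}

run_ring_metrics <- function(config) {
  cfg <- merge_config(list(input = NULL, chains = NULL, marker_residue = 38,
                           dimer_residue = 36, square_threshold = 2.0,
                           split_cutoff = 60, id = NULL), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  atoms <- read_structure(cfg$input)
  ring <- build_ring(atoms, chains = cfg$chains, split_cutoff = cfg$split_cutoff)
  id <- cfg$id %||% attr(atoms, "structure_id")
  m <- ring_metrics(ring, marker_residue = cfg$marker_residue,
                    dimer_residue = cfg$dimer_residue,
                    threshold = cfg$square_threshold, id = id)
  row <- m %>%
    mutate(diagonals = vapply(.data$diagonals, paste, "", collapse = ","),
           intra_dimer = vapply(.data$intra_dimer,
                                function(v) paste(round(v, 3), collapse = ","),
                                ""))
  list(config = cfg[names(cfg) != "chains"],
       report = list(metrics = as.list(row)),
       tables = list(metrics = row))
}

run_cluster <- function(config) {
  cfg <- merge_config(list(input = NULL, cluster_cutoff = 3.8,
                           linkage = "complete"), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  items <- readr::read_tsv(cfg$input, show_col_types = FALSE)
  out <- cluster_conformations(items, linkage = cfg$linkage,
                               cutoff = cfg$cluster_cutoff)
  list(config = cfg,
       report = list(n_groups = max(out$group), items = nrow(out)),
       tables = list(groups = out))
}

run_metal_site <- function(config) {
  cfg <- merge_config(list(input = NULL, center = "MG", shell_cutoff = 3.0,
                           donor_elements = c("O", "N"),
                           b_ratio_flag = 1.2), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  atoms <- read_structure(cfg$input)
  shell <- find_shell(atoms, center = cfg$center, cutoff = cfg$shell_cutoff,
                      donor_elements = cfg$donor_elements)
  geo <- assess_geometry(shell)
  scores <- score_identity(shell, b_ratio_flag = cfg$b_ratio_flag)
  list(config = cfg,
       report = list(
         cn = shell$cn,
         center = shell$center,
         geometry = as.list(geo),
         identity = lapply(seq_len(nrow(scores)), function(i) as.list(scores[i, ])),
         b_ratio = attr(scores, "b_ratio"),
         lighter_ion_suspected = attr(scores, "lighter_ion_suspected")
       ),
       tables = list(shell = shell$donors, identity = scores))
}

run_motif <- function(config) {
  cfg <- merge_config(list(input = NULL, spacer_range = c(17L, 18L)), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  seqs <- read_sequences(cfg$input)
  hits <- scan_nbs_motif(seqs, spacer_range = cfg$spacer_range)
  list(config = cfg,
       report = list(n_sequences = nrow(seqs), n_hits = nrow(hits)),
       tables = list(hits = hits))
}

run_conserve <- function(config) {
  cfg <- merge_config(list(input = NULL, format = "fasta",
                           reference_id = NULL, position = NULL,
                           column = NULL, target_residues = "E"), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  aln <- read_alignment(cfg$input, format = cfg$format)
  column <- cfg$column
  if (is.null(column)) {
    if (is.null(cfg$reference_id) || is.null(cfg$position)) {
      abort("give either `column` or `reference_id` + `position`",
            class = "rck_usage_error")
    }
    column <- map_reference_position(aln, cfg$reference_id, cfg$position)
  }
  cons <- column_conservation(aln, column, target_residues = cfg$target_residues)
  ctx <- if (column >= 2L) context_motif(aln, column) else NULL
  list(config = cfg,
       report = list(column = column,
                     percent_identity = cons$percent_identity,
                     target_count = cons$target_count,
                     n_rows = cons$n_rows, gap_count = cons$gap_count),
       tables = c(list(conservation = cons %>% select(-"counts"),
                       residues = cons$counts[[1]]),
                  if (!is.null(ctx)) list(context = ctx)))
}

run_flux_fit <- function(config) {
  cfg <- merge_config(list(input = NULL, cccp_time = 100,
                           valinomycin_time = NULL,
                           normalization = "steady_state", x0 = NULL,
                           model = "auto", delta = 2), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  trace <- read_flux_trace(cfg$input, cccp_time = cfg$cccp_time,
                           valinomycin_time = cfg$valinomycin_time)
  norm <- normalize_trace(trace, mode = cfg$normalization)
  fit <- if (identical(cfg$model, "auto")) {
    f1 <- fit_exponential(norm, order = 1L, x0 = cfg$x0)
    f2 <- tryCatch(fit_exponential(norm, order = 2L, x0 = cfg$x0),
                   error = function(e) NULL)
    if (is.null(f2)) f1 else select_model(f1, f2, delta = cfg$delta)
  } else {
    fit_exponential(norm, order = as.integer(cfg$model), x0 = cfg$x0)
  }
  rate <- extract_rate(fit)
  summary <- dplyr::bind_cols(
    tibble(input = cfg$input, order = fit$order), rate,
    tibble(sse = fit$sse, aicc = fit$aicc, n = fit$n)
  )
  list(config = cfg,
       report = list(order = fit$order, parameters = as.list(fit$pars),
                     k = rate$k, component = rate$component,
                     fast_dominant = rate$fast_dominant,
                     sse = fit$sse, aicc = fit$aicc, n = fit$n),
       tables = list(summary = summary))
}

run_titrate <- function(config) {
  cfg <- merge_config(list(input = NULL), config)
  if (is.null(cfg$input)) abort("`input` is required", class = "rck_usage_error")
  series <- readr::read_csv(cfg$input, show_col_types = FALSE, progress = FALSE)
  res <- fit_hill_replicates(series)
  list(config = cfg,
       report = list(parameters = as.list(setNames(res$summary$mean,
                                                   res$summary$term)),
                     sd = as.list(setNames(res$summary$sd, res$summary$term)),
                     n_replicates = res$summary$n_replicates[1]),
       tables = list(hill = res$summary))
}

run_sim_ring <- function(config) {
  cfg <- merge_config(list(L1 = 30, L2 = 30, dimer_d36 = NULL,
                           noise_sigma = 0, seed = 1L, output = NULL), config)
  atoms <- simulate_ring(cfg$L1, cfg$L2, dimer_d36 = cfg$dimer_d36,
                         noise_sigma = cfg$noise_sigma, seed = cfg$seed)
  if (!is.null(cfg$output)) write_structure_pdb(atoms, cfg$output)
  list(config = cfg, report = list(n_atoms = nrow(atoms),
                                   output = cfg$output),
       tables = list())
}

run_sim_site <- function(config) {
  cfg <- merge_config(list(ion = "MG", cn = 6L, distance = 2.07,
                           geometry = "octahedral", jitter_dist = 0,
                           jitter_ang = 0, b_center = 30, b_donors = 30,
                           seed = 1L, output = NULL), config)
  atoms <- simulate_metal_site(cfg$ion, cfg$cn, cfg$distance, cfg$geometry,
                               cfg$jitter_dist, cfg$jitter_ang,
                               cfg$b_center, cfg$b_donors, cfg$seed)
  if (!is.null(cfg$output)) write_structure_pdb(atoms, cfg$output)
  list(config = cfg, report = list(n_atoms = nrow(atoms),
                                   output = cfg$output),
       tables = list())
}

run_sim_alignment <- function(config) {
  cfg <- merge_config(list(n_rows = 15L, length = 60L, column_spec = list(),
                           exact_counts = FALSE, embed_nbs_motif = FALSE,
                           motif_start = 1L, seed = 1L, output = NULL), config)
  aln <- simulate_alignment(cfg$n_rows, cfg$length, cfg$column_spec,
                            cfg$exact_counts, cfg$embed_nbs_motif,
                            cfg$motif_start, cfg$seed)
  if (!is.null(cfg$output)) write_alignment_fasta(aln, cfg$output)
  list(config = cfg[names(cfg) != "column_spec"],
       report = list(n_rows = nrow(aln), output = cfg$output),
       tables = list())
}

run_sim_trace <- function(config) {
  cfg <- merge_config(list(k_fast = 0.096, k_slow = NULL, amp_fast = 1,
                           floor = 0.2, noise_sigma = 0.01, cccp_time = 100,
                           decay_duration = 400, valinomycin = FALSE,
                           dt = 2, seed = 1L, output = NULL), config)
  trace <- simulate_flux_trace(cfg$k_fast, cfg$k_slow, cfg$amp_fast,
                               cfg$floor, cfg$noise_sigma, cfg$cccp_time,
                               cfg$decay_duration, cfg$valinomycin, cfg$dt,
                               seed = cfg$seed)
  if (!is.null(cfg$output)) {
    readr::write_csv(trace %>% rename(time_s = "time"), cfg$output)
  }
  list(config = cfg, report = list(n_points = nrow(trace),
                                   output = cfg$output),
       tables = list())
}

run_sim_titration <- function(config) {
  cfg <- merge_config(list(k_half = 155, n_hill = 1.8, start = 0.01,
                           end = 0.10,
                           conc = c(0, 25, 50, 100, 200, 400, 800, 1500, 2000),
                           unit = "uM", noise_sigma = 0.05,
                           n_replicates = 3L, seed = 1L, output = NULL), config)
  series <- simulate_titration(cfg$k_half, cfg$n_hill, cfg$start, cfg$end,
                               cfg$conc, cfg$unit, cfg$noise_sigma,
                               cfg$n_replicates, cfg$seed)
  if (!is.null(cfg$output)) readr::write_csv(series, cfg$output)
  list(config = cfg, report = list(n_rows = nrow(series),
                                   output = cfg$output),
       tables = list())
}
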