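#' Run the volatile/sequence-variation analysis pipeline
#'
#' Orchestrates the analysis stages in dependency order: `simulate` (write
#' synthetic fixtures), `quantify` (peak tables to contents/percentages),
#' `classify` (odor-class aggregation and aroma grouping), `callvars` (SNP
#' and InDel calling with isoform grouping), `diversity` (within-group
#' nucleotide and haplotype diversity), `splice` (cDNA-to-gDNA gene models,
#' GT-AG validation, splice events) and `gra` (gray relational association
#' of sites with emissions). Each stage writes its outputs into `outdir`
#' before the next stage reads them; disabling a stage never alters the
#' outputs of enabled stages. With an unchanged seed and inputs, re-running
#' reproduces identical outputs.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{outdir}{Output directory (required).}
#'     \item{stages}{Character vector of stages to run; default all.}
#'     \item{seed}{Seed for the `simulate` stage (default 1).}
#'     \item{sim}{Named list of [sim_config()] overrides.}
#'     \item{inputs}{Named list of input paths (`peaks_csv`, `odor_map_csv`,
#'       `rules_yaml`, `ref_fasta`, `panel_fasta`, `groups_tsv`,
#'       `gdna_fasta`, `cdnas_fasta`, `sites_csv`, `emissions_csv`); by
#'       default the `simulate` outputs in `outdir`.}
#'     \item{rho}{Distinguishing coefficient for the `gra` stage (default
#'       0.5).}
#'     \item{normalize}{GRA normalization (default `"minmax"`).}
#'   }
#' @return List of class `pipeline_report` with one summary element per
#'   executed stage (compound/group counts, SNP and InDel counts, the
#'   diversity table, top GRD sites) plus the effective config.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config$outdir is required")
  all_stages <- c("simulate", "quantify", "classify", "callvars",
                  "diversity", "splice", "gra")
  stages <- if (is.null(config$stages)) all_stages else config$stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # ---- validation before any stage runs ----------------------------------
  sim_args <- c(list(seed = seed), config$sim)
  if ("simulate" %in% stages) {
    if (!is.null(sim_args$n_cultivars) && sim_args$n_cultivars < 1) {
      stop("validation: empty cultivar set (n_cultivars < 1)")
    }
    sc <- do.call(sim_config, sim_args)
  }
  inputs <- config$inputs
  path_of <- function(key, default) {
    if (!is.null(inputs[[key]])) inputs[[key]] else file.path(config$outdir,
                                                              default)
  }
  need_input <- function(key, default, stage) {
    p <- path_of(key, default)
    if (!file.exists(p)) {
      stop("validation: stage '", stage, "' needs input '", key,
           "' but ", p, " does not exist")
    }
    p
  }
  if (!("simulate" %in% stages)) {
    # simulate would create the default inputs; without it they must exist
    # up front, except those produced by an earlier enabled stage
    for (stage in setdiff(stages, "simulate")) {
      defaults <- switch(stage,
        quantify = c(peaks_csv = "peaks.csv"),
        classify = c(peaks_csv = "peaks.csv"),
        callvars = c(ref_fasta = "reference.fasta",
                     panel_fasta = "panel.fasta"),
        diversity = c(panel_fasta = "panel.fasta",
                      groups_tsv = "groups.tsv"),
        splice = c(gdna_fasta = "gdna.fasta", cdnas_fasta = "cdnas.fasta"),
        gra = c(sites_csv = "sites.csv", emissions_csv = "emissions.csv"))
      for (key in names(defaults)) {
        if (key == "groups_tsv" && "callvars" %in% stages) next
        need_input(key, defaults[[key]], stage)
      }
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = stages, seed = seed)

  # ---- simulate ----------------------------------------------------------
  if ("simulate" %in% stages) {
    locus <- generate_locus(sc)
    panel <- generate_haplotype_panel(sc, locus)
    emis <- generate_emissions(sc, panel)
    write_fasta(setNames(locus$gdna$seq, locus$gdna$id),
                file.path(config$outdir, "gdna.fasta"))
    write_fasta(setNames(vapply(locus$cdnas, `[[`, "", "seq"),
                         vapply(locus$cdnas, `[[`, "", "id")),
                file.path(config$outdir, "cdnas.fasta"))
    write_fasta(setNames(locus$cdnas$canonical$seq, locus$cdnas$canonical$id),
                file.path(config$outdir, "reference.fasta"))
    write_fasta(panel$sequences, file.path(config$outdir, "panel.fasta"))
    write.csv(emis$peaks, file.path(config$outdir, "peaks.csv"),
              row.names = FALSE)
    write.csv(data.frame(cultivar = rownames(emis$emissions),
                         emis$emissions, check.names = FALSE),
              file.path(config$outdir, "emissions.csv"), row.names = FALSE)
    write.csv(data.frame(cultivar = rownames(panel$truth$incidence),
                         panel$truth$incidence, check.names = FALSE),
              file.path(config$outdir, "sites.csv"), row.names = FALSE)
    truth <- list(seed = seed, S = panel$truth$S,
                  n_snp_sites = length(panel$truth$snp_positions),
                  n_snp_variants = length(unique(sprintf("%d%s",
                    panel$truth$snp_variants$pos,
                    panel$truth$snp_variants$alt))),
                  carriers = sum(panel$truth$carriers),
                  causal_site = emis$truth$causal_site,
                  causal_compound = emis$truth$causal_compound,
                  orf_nt = as.list(locus$truth$orf_nt))
    jsonlite::write_json(truth, file.path(config$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    report$simulate <- truth
  }

  # ---- quantify ----------------------------------------------------------
  if ("quantify" %in% stages) {
    peaks_path <- need_input("peaks_csv", "peaks.csv", "quantify")
    tables <- read_peak_tables(peaks_path)
    profiles <- lapply(tables, quantify_content)
    .write_tsv(profiles_to_table(profiles),
               file.path(config$outdir, "profiles.tsv"))
    report$quantify <- list(n_cultivars = length(profiles),
                            n_compounds = length(unique(unlist(lapply(
                              profiles, function(p) names(p$contents))))),
                            major_compounds = select_major_compounds(profiles))
  }

  # ---- classify ----------------------------------------------------------
  if ("classify" %in% stages) {
    if (!("quantify" %in% stages)) {
      peaks_path <- need_input("peaks_csv", "peaks.csv", "classify")
      profiles <- lapply(read_peak_tables(peaks_path), quantify_content)
    }
    omap_path <- if (!is.null(inputs$odor_map_csv)) inputs$odor_map_csv else
      system.file("extdata", "odor_map.csv", package = "scentvar")
    rules <- if (!is.null(inputs$rules_yaml)) {
      default_aroma_rules(inputs$rules_yaml)
    } else default_aroma_rules()
    omap <- read_odor_map(omap_path)
    aromas <- lapply(profiles, function(p) {
      a <- aggregate_odor_classes(p, omap)
      a$group <- classify_aroma(a, rules)
      a
    })
    .write_tsv(aromas_to_table(aromas), file.path(config$outdir, "aroma.tsv"))
    report$classify <- list(groups = table(vapply(aromas, `[[`, "", "group")))
  }

  # ---- callvars ----------------------------------------------------------
  if ("callvars" %in% stages) {
    ref_path <- need_input("ref_fasta", "reference.fasta", "callvars")
    panel_path <- need_input("panel_fasta", "panel.fasta", "callvars")
    ref <- read_fasta(ref_path)[1]
    queries <- read_fasta(panel_path)
    calls <- lapply(names(queries), function(id) {
      v <- call_variants(ref[[1]], queries[[id]], ref_id = names(ref))
      v <- annotate_effects(ref[[1]], v)
      v$query_id <- id
      v
    })
    vtab <- do.call(rbind, calls)
    .write_tsv(vtab, file.path(config$outdir, "variants.tsv"))
    groups <- vapply(calls, function(v) assign_isoform_group(v)$label,
                     character(1))
    gtab <- data.frame(query_id = names(queries), group = groups,
                       stringsAsFactors = FALSE)
    .write_tsv(gtab, file.path(config$outdir, "groups.tsv"))
    snp <- vtab[vtab$kind == "SNP", , drop = FALSE]
    uniq_snp <- unique(snp[, c("pos", "ref", "alt", "effect")])
    report$callvars <- list(
      n_queries = length(queries),
      n_snp_sites = length(unique(snp$pos)),
      n_snp_alleles = nrow(uniq_snp),
      n_synonymous = sum(uniq_snp$effect == "synonymous"),
      n_nonsynonymous = sum(uniq_snp$effect == "nonsynonymous"),
      indel_lengths = sort(unique(nchar(
        ifelse(vtab$kind == "insertion", vtab$alt,
               ifelse(vtab$kind == "deletion", vtab$ref, ""))))),
      groups = table(groups))
    report$callvars$indel_lengths <-
      report$callvars$indel_lengths[report$callvars$indel_lengths > 0]
  }

  # ---- diversity ---------------------------------------------------------
  if ("diversity" %in% stages) {
    panel_path <- need_input("panel_fasta", "panel.fasta", "diversity")
    groups_path <- need_input("groups_tsv", "groups.tsv", "diversity")
    seqs <- read_fasta(panel_path)
    gtab <- .read_tsv(groups_path)
    rows <- lapply(split(gtab$query_id, gtab$group), function(ids) ids)
    div <- do.call(rbind, Filter(Negate(is.null),
      lapply(names(rows), function(gname) {
        ids <- rows[[gname]]
        if (length(ids) < 2) return(NULL)
        diversity_stats(seqs[ids], group = gname)
      })))
    .write_tsv(div, file.path(config$outdir, "diversity.tsv"))
    report$diversity <- div
  }

  # ---- splice ------------------------------------------------------------
  if ("splice" %in% stages) {
    gdna_path <- need_input("gdna_fasta", "gdna.fasta", "splice")
    cdnas_path <- need_input("cdnas_fasta", "cdnas.fasta", "splice")
    gdna <- read_fasta(gdna_path)
    cdnas <- read_fasta(cdnas_path)
    models <- lapply(names(cdnas), function(id) {
      map_cdna(list(id = names(gdna)[1], seq = gdna[[1]]),
               list(id = id, seq = cdnas[[id]]))
    })
    names(models) <- names(cdnas)
    write_gene_model_gff3(models, file.path(config$outdir, "models.gff3"))
    events <- do.call(rbind, lapply(models[-1], function(m) {
      compare_isoforms(models[[1]], m)
    }))
    if (is.null(events)) events <- compare_isoforms(models[[1]], models[[1]])
    .write_tsv(events, file.path(config$outdir, "events.tsv"))
    report$splice <- list(
      n_exons = vapply(models, function(m) nrow(m$exons), integer(1)),
      gt_ag = vapply(models, function(m) all(validate_canonical_sites(m)$is_GT_AG),
                     logical(1)),
      events = events)
  }

  # ---- gra ---------------------------------------------------------------
  if ("gra" %in% stages) {
    sites_path <- need_input("sites_csv", "sites.csv", "gra")
    emis_path <- need_input("emissions_csv", "emissions.csv", "gra")
    sdf <- read.csv(sites_path, check.names = FALSE)
    edf <- read.csv(emis_path, check.names = FALSE)
    sm <- as.matrix(sdf[, -1, drop = FALSE])
    rownames(sm) <- sdf[[1]]
    em <- as.matrix(edf[, -1, drop = FALSE])
    rownames(em) <- edf[[1]]
    common <- intersect(rownames(sm), rownames(em))
    dropped <- setdiff(union(rownames(sm), rownames(em)), common)
    if (length(dropped)) {
      message("dropping ", length(dropped),
              " cultivar(s) without both sequence and emission records")
    }
    rho <- if (is.null(config$rho)) 0.5 else config$rho
    normalize <- if (is.null(config$normalize)) "minmax" else config$normalize
    res <- gra(sm[common, , drop = FALSE], em[common, , drop = FALSE],
               rho = rho, normalize = normalize)
    write.csv(data.frame(site = rownames(res$grd), res$grd,
                         check.names = FALSE),
              file.path(config$outdir, "grd.csv"), row.names = FALSE)
    long <- do.call(rbind, lapply(colnames(res$grd), function(cc) {
      r <- rank_sites(res, cc)
      r$compound <- cc
      r
    }))
    .write_tsv(long[, c("site", "compound", "grd", "rank")],
               file.path(config$outdir, "grd_long.tsv"))
    top <- long[long$rank == 1, c("compound", "site", "grd")]
    report$gra <- list(rho = rho, normalize = normalize, top_sites = top,
                       n_dropped_cultivars = length(dropped))
  }

  class(report) <- "pipeline_report"
  report
}
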