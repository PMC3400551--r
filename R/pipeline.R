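#' Pipeline configuration
#'
#' Collects every input path, chain id, and numeric threshold of the
#' full binding-site mapping pipeline. Unknown keys are rejected; all
#' thresholds default to the pipeline's standard values (backbone clash
#' 2.0 A, heavy-atom contact 4.6 A, conservation tiers 0.8/0.5, relative
#' SASA 0.25, partner distance 10 A) and are echoed into the report for
#' provenance.
#'
#' @param context Path to the context-assembly PDB (required).
#' @param receptor Path to the docking-frame receptor PDB (required).
#' @param ligand Path to the ligand PDB (required).
#' @param poses Path to a pose table (see [read_poses()]); alternatively
#'   set `enumerate` to sample poses internally.
#' @param partner Optional path to the partner-assembly PDB.
#' @param alignment Optional path to an MSA (FASTA or Clustal).
#' @param alignment_format `"fasta"` or `"clustal"`.
#' @param annotations Optional path to a residue-annotation table.
#' @param anchor_chain Anchor chain id in the context assembly (required).
#' @param reference_row Reference row id of the MSA (maps columns onto the
#'   anchor chain).
#' @param enumerate Optional list `list(n_rotations =, n_translations =)`
#'   to generate poses with [enumerate_poses()] instead of importing.
#' @param clash_cutoff,contact_cutoff,tier_high,tier_moderate Numeric
#'   thresholds (Angstrom for the cutoffs; score units for the tiers).
#' @param rel_sasa_min,partner_dist_max,sasa_n_points Exposure parameters,
#'   see [exposure_params()].
#' @param exclude_anchor Exclude the anchor chain from the clash context
#'   (default `TRUE`).
#' @param seed Integer seed for any internal sampling.
#' @param out_dir Output directory for report files (`NULL` = no files).
#' @param ... Unknown keys, collected so validation can reject them by
#'   name (config files with typos fail loudly, not silently).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(context, receptor, ligand, poses = NULL,
                            partner = NULL, alignment = NULL,
                            alignment_format = "fasta", annotations = NULL,
                            anchor_chain, reference_row = NULL,
                            enumerate = NULL,
                            clash_cutoff = 2.0, contact_cutoff = 4.6,
                            tier_high = 0.8, tier_moderate = 0.5,
                            rel_sasa_min = 0.25, partner_dist_max = 10,
                            sasa_n_points = 960, exclude_anchor = TRUE,
                            seed = 1, out_dir = NULL, ...) {
  extra <- list(...)
  cfg <- list(context = context, receptor = receptor, ligand = ligand,
              poses = poses, partner = partner, alignment = alignment,
              alignment_format = alignment_format, annotations = annotations,
              anchor_chain = anchor_chain, reference_row = reference_row,
              enumerate = enumerate, clash_cutoff = clash_cutoff,
              contact_cutoff = contact_cutoff, tier_high = tier_high,
              tier_moderate = tier_moderate, rel_sasa_min = rel_sasa_min,
              partner_dist_max = partner_dist_max,
              sasa_n_points = sasa_n_points, exclude_anchor = exclude_anchor,
              seed = seed, out_dir = out_dir)
  validate_pipeline_config(c(cfg, extra))
}

PIPELINE_KEYS <- c("context", "receptor", "ligand", "poses", "partner",
                   "alignment", "alignment_format", "annotations",
                   "anchor_chain", "reference_row", "enumerate",
                   "clash_cutoff", "contact_cutoff", "tier_high",
                   "tier_moderate", "rel_sasa_min", "partner_dist_max",
                   "sasa_n_points", "exclude_anchor", "seed", "out_dir")

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in c("context", "receptor", "ligand", "anchor_chain")) {
    if (is.null(cfg[[key]])) abort(paste0("config is missing '", key, "'"))
  }
  for (key in c("context", "receptor", "ligand", "poses", "partner",
                "alignment", "annotations")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(paste0("config '", key, "': no such file: ", cfg[[key]]))
    }
  }
  if (is.null(cfg$poses) && is.null(cfg$enumerate)) {
    abort("config needs either 'poses' (a pose table) or 'enumerate'")
  }
  stopifnot(cfg$clash_cutoff > 0, cfg$contact_cutoff > cfg$clash_cutoff,
            cfg$tier_high > cfg$tier_moderate)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration file
#'
#' YAML mapping with the keys of [pipeline_config()]; relative paths are
#' resolved against the file's directory.
#'
#' @param path Config file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("context", "receptor", "ligand", "poses", "partner",
                "alignment", "annotations")) {
    if (!is.null(raw[[key]]) && !startsWith(raw[[key]], "/")) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(pipeline_config, raw)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full binding-site mapping pipeline
#'
#' Stages, each skippable via `stages`:
#' * `select` — load structures and poses, superpose the receptor onto
#'   the anchor chain, screen poses in score order, select the first
#'   clash-free pose;
#' * `interface` — residue contacts of the placed ligand with the anchor
#'   chain, bridge overlap and mutagenesis consistency (if annotations);
#' * `conserve` — conservation profile, column-to-residue map (if an
#'   alignment is given);
#' * `epitope` — interface exposure and candidate epitope residues;
#' * `partner` — steric-overlap verdict against the partner assembly.
#'
#' Earlier stages a requested stage depends on are run automatically.
#' With `out_dir` set, results are serialized as JSON and TSV; reruns
#' with the same config produce byte-identical files (timestamps appear
#' only in the log, which goes to standard error).
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("select", "interface", "conserve", "epitope", "partner")`.
#' @return A list of class `pipeline_report` with the per-stage results
#'   and the echoed config.
#' @export
run_pipeline <- function(config,
                         stages = c("select", "interface", "conserve",
                                    "epitope", "partner")) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- function(s) s %in% stages
  if (need("interface") || need("epitope") || need("partner")) {
    stages <- union(stages, "select")
  }
  if (need("epitope")) stages <- union(stages, "conserve")

  res <- list(schema_version = "1",
              config = unclass(config)[!vapply(config, is.null, logical(1))])

  pipeline_log("loading structures")
  context <- with_stage("load", read_pdb(config$context))
  receptor <- with_stage("load", read_pdb(config$receptor))
  ligand <- with_stage("load", read_pdb(config$ligand))
  partner <- if (!is.null(config$partner)) {
    with_stage("load", read_pdb(config$partner))
  }

  selection <- NULL
  if ("select" %in% stages) {
    pipeline_log("screening poses")
    poses <- with_stage("select", {
      if (!is.null(config$poses)) {
        read_poses(config$poses)
      } else {
        enumerate_poses(receptor, ligand,
                        config$enumerate$n_rotations,
                        config$enumerate$n_translations,
                        seed = config$seed)
      }
    })
    fit <- with_stage("select",
                      anchor_superpose(receptor, context,
                                       config$anchor_chain))
    selection <- with_stage("select", select_first_clashfree(
      poses, ligand, fit, context,
      clash_params(clash_cutoff = config$clash_cutoff),
      anchor_chain = if (config$exclude_anchor) config$anchor_chain
    ))
    res$selection <- selection
    res$anchor_rmsd <- fit$rmsd
  }

  annotations <- if (!is.null(config$annotations)) {
    with_stage("interface", read_annotations(config$annotations))
  }

  contacts <- NULL
  if ("interface" %in% stages && isTRUE(selection$admissible)) {
    pipeline_log("mapping the interface")
    anchor_atoms <- dplyr::filter(context,
                                  .data$chain == config$anchor_chain)
    contacts <- with_stage("interface", interface_contacts(
      selection$placed, anchor_atoms, cutoff = config$contact_cutoff))
    res$contacts <- contacts
    if (!is.null(annotations)) {
      res$bridge_overlap <- with_stage("interface",
                                       bridge_overlap(contacts, annotations))
      if (any(startsWith(annotations$tag, "mutagenesis:"))) {
        res$mutagenesis <- with_stage(
          "interface", mutagenesis_consistency(contacts, annotations))
      }
    }
  }

  profile <- NULL
  colmap <- NULL
  if ("conserve" %in% stages && !is.null(config$alignment)) {
    pipeline_log("scoring conservation")
    aln <- with_stage("conserve", read_alignment(config$alignment,
                                                 config$alignment_format))
    profile <- with_stage("conserve", conservation_profile(
      aln, tiers = c(high = config$tier_high,
                     moderate = config$tier_moderate)))
    res$conservation <- profile
    if (!is.null(config$reference_row)) {
      anchor_res <- residues(dplyr::filter(context,
                                           .data$chain ==
                                             config$anchor_chain))
      colmap <- with_stage("conserve", map_columns_to_residues(
        aln, config$reference_row, anchor_res))
      res$column_map <- colmap
    }
  }

  if ("epitope" %in% stages && !is.null(profile) && !is.null(colmap)) {
    pipeline_log("calling candidate epitope residues")
    exposure <- with_stage("epitope", suppressWarnings(interface_exposure(
      context, partner, chain = config$anchor_chain,
      params = exposure_params(rel_sasa_min = config$rel_sasa_min,
                               partner_dist_max = config$partner_dist_max,
                               sasa_n_points = config$sasa_n_points))))
    res$exposure <- exposure
    res$epitope <- with_stage("epitope", candidate_epitope(
      profile, colmap, exposure, contact_map = contacts))
  }

  if ("partner" %in% stages && !is.null(partner) &&
      isTRUE(selection$admissible)) {
    pipeline_log("checking partner overlap")
    res$partner_overlap <- with_stage("partner", partner_overlap(
      selection$placed, partner,
      clash_params(clash_cutoff = config$clash_cutoff)))
  }

  class(res) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(res, config$out_dir)
  res
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Serialize a pipeline report
#'
#' Writes `report.json` plus TSVs (`clash_table.tsv`, `contacts.tsv`,
#' `conservation.tsv`, `epitope.tsv` as available) under `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  js <- list(schema_version = report$schema_version, config = report$config)
  if (!is.null(report$selection)) {
    js$selected_rank <- report$selection$selected_rank
    js$admissible <- report$selection$admissible
    js$clash_table <- as.data.frame(report$selection$reports)
    tsv(report$selection$reports, "clash_table.tsv")
  }
  if (!is.null(report$contacts)) {
    js$contacts <- as.data.frame(report$contacts)
    tsv(report$contacts, "contacts.tsv")
  }
  if (!is.null(report$bridge_overlap)) {
    js$bridge_overlap <- as.data.frame(report$bridge_overlap)
  }
  if (!is.null(report$mutagenesis)) {
    js$mutagenesis <- report$mutagenesis[c("tp", "fp", "fn", "tn")]
    js$mutagenesis$residues <- as.data.frame(report$mutagenesis$table)
  }
  if (!is.null(report$conservation)) {
    js$conservation <- as.data.frame(report$conservation)
    tsv(report$conservation, "conservation.tsv")
  }
  if (!is.null(report$epitope)) {
    js$epitope <- as.data.frame(report$epitope)
    tsv(report$epitope, "epitope.tsv")
  }
  if (!is.null(report$partner_overlap)) {
    js$partner_overlap <- list(
      blocked = report$partner_overlap$blocked,
      clash_count = report$partner_overlap$clash_count,
      min_backbone_distance = report$partner_overlap$min_backbone_distance)
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> schema", x$schema_version, "\n")
  if (!is.null(x$selection)) print(x$selection)
  if (!is.null(x$contacts)) {
    cat(sprintf("  %d interface residue contact(s)\n", nrow(x$contacts)))
  }
  if (!is.null(x$epitope)) {
    cat(sprintf("  %d candidate epitope residue(s)\n", nrow(x$epitope)))
  }
  if (!is.null(x$partner_overlap)) {
    cat(sprintf("  partner joining %s\n",
                if (x$partner_overlap$blocked) "BLOCKED" else "not blocked"))
  }
  invisible(x)
}
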