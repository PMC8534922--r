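#' Build a pipeline run configuration
#'
#' Collects input paths (or in-memory objects), stage toggles and stage
#' parameters for [run_pipeline()].  Defaults mirror the package's
#' documented defaults for each stage.
#'
#' @param alignment path to a FASTA/Clustal alignment, or an `aln` object.
#' @param isoform_map path to a seq_id/species/isoform TSV, or a data
#'   frame.
#' @param ref1,ref2 reference sequence ids for isoform 1 and isoform 2.
#' @param out_dir report directory.
#' @param domains optional domain annotation TSV path or data frame.
#' @param outgroup optional character vector of leaf ids used to root the
#'   joint tree for ancestral reconstruction.
#' @param stages character subset of
#'   `c("conserve", "tree", "motifs", "ancestral")`.
#' @param correction distance correction for trees (`"poisson"` or
#'   `"p"`).
#' @param min_cons,min_len,max_violations motif-calling thresholds.
#' @param background,pseudocount logo parameters.
#' @param model_pi `"uniform"` or `"empirical"` stationary frequencies for
#'   ancestral reconstruction.
#' @param aln_format `"fasta"` or `"clustal"`.
#' @param seed integer seed recorded in the log (the stages themselves are
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(alignment, isoform_map, ref1, ref2, out_dir,
                       domains = NULL, outgroup = NULL,
                       stages = c("conserve", "tree", "motifs", "ancestral"),
                       correction = "poisson", min_cons = 0.5,
                       min_len = 10L, max_violations = 2L,
                       background = NULL, pseudocount = 0,
                       model_pi = "uniform", aln_format = "fasta",
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(alignment) && !file.exists(alignment))
    stop("alignment file does not exist: ", alignment)
  if (is.character(isoform_map) && !file.exists(isoform_map))
    stop("isoform map file does not exist: ", isoform_map)
  if (is.character(domains) && !is.null(domains) && !file.exists(domains))
    stop("domain file does not exist: ", domains)
  if (!model_pi %in% c("uniform", "empirical"))
    stop("model_pi must be 'uniform' or 'empirical'")
  structure(list(alignment = alignment, isoform_map = isoform_map,
                 ref1 = ref1, ref2 = ref2, out_dir = out_dir,
                 domains = domains, outgroup = outgroup, stages = stages,
                 correction = correction, min_cons = min_cons,
                 min_len = min_len, max_violations = max_violations,
                 background = background, pseudocount = pseudocount,
                 model_pi = model_pi, aln_format = aln_format,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full paralog-divergence pipeline
#'
#' Executes the enabled stages on a joint two-isoform alignment and writes
#' a report directory: `profile.tsv` (conservation profile),
#' `domain_summary.tsv` (when domains are given), `tree_joint.nwk` /
#' `tree_iso1.nwk` / `tree_iso2.nwk`, `motifs.tsv` and `logo_*.tsv`,
#' `ancestors.fasta` + `ancestors.tsv`, and `run.log` with a full
#' parameter echo.  Given identical inputs and configuration the outputs
#' are identical.
#'
#' @param config a `run_config`.
#' @return the report directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logpath <- file.path(config$out_dir, "run.log")
  logcon <- file(logpath, "w")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, logcon)
    message(msg)
  }
  say("paraloglens pipeline, package version ",
      as.character(utils::packageVersion("paraloglens")))
  prm <- config[setdiff(names(config), c("alignment", "isoform_map",
                                         "domains"))]
  say("parameters: ",
      paste(names(prm), vapply(prm, function(x)
        paste(format(unlist(x)), collapse = ","), character(1)),
        sep = "=", collapse = " "))

  aln <- if (inherits(config$alignment, "aln")) config$alignment else
    read_alignment(config$alignment, config$aln_format)
  map <- if (is.data.frame(config$isoform_map)) config$isoform_map else
    read_isoform_map(config$isoform_map)
  mapv <- normalize_isoform_map(map)
  domains <- if (is.character(config$domains)) read_domain_tsv(config$domains)
             else config$domains
  say("alignment: ", length(aln$ids), " sequences x ", n_cols(aln),
      " columns")

  stage <- function(name, expr) {
    if (!name %in% config$stages) {
      say("stage ", name, ": skipped (disabled)")
      return(invisible(NULL))
    }
    say("stage ", name, ": running")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  profile <- stage("conserve", {
    prof <- conservation_profile(aln, mapv, config$ref1, config$ref2)
    profile_to_tsv(prof, file.path(config$out_dir, "profile.tsv"))
    if (!is.null(domains)) {
      ds <- domain_identity_summary(prof, domains)
      utils::write.table(ds, file.path(config$out_dir, "domain_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    prof
  })

  joint_tree <- stage("tree", {
    corr <- config$correction
    dm <- distance_matrix(aln, corr)
    joint_tree <- me_tree(dm)
    write_newick(joint_tree, file.path(config$out_dir, "tree_joint.nwk"))
    for (iso in c("ISO1", "ISO2")) {
      ids <- intersect(aln$ids, names(mapv)[mapv == iso])
      if (length(ids) >= 3L) {
        sub <- aln_subset(aln, ids)
        tr <- me_tree(distance_matrix(sub, corr))
        write_newick(tr, file.path(config$out_dir,
                                   paste0("tree_", tolower(iso), ".nwk")))
      } else say("  ", iso, ": fewer than 3 sequences, tree skipped")
    }
    joint_tree
  })

  stage("motifs", {
    if (is.null(profile))
      profile <- conservation_profile(aln, mapv, config$ref1, config$ref2)
    calls <- call_motifs(profile, config$min_cons, config$min_len,
                         config$max_violations)
    logos <- list()
    if (nrow(calls)) {
      w <- henikoff_weights(aln)
      iso_ids <- list(ISO1 = intersect(aln$ids, names(mapv)[mapv == "ISO1"]),
                      ISO2 = intersect(aln$ids, names(mapv)[mapv == "ISO2"]))
      for (k in seq_len(nrow(calls))) {
        iso <- calls$isoform[k]
        sub <- aln_subset(aln, iso_ids[[iso]], drop_allgap = FALSE)
        logos[[paste0(iso, "_", calls$motif[k])]] <-
          logo_matrix(sub, calls$col_start[k]:calls$col_end[k],
                      background = config$background,
                      pseudocount = config$pseudocount)
      }
    }
    motif_report(calls, logos, config$out_dir, profile = profile)
    say("  ", length(unique(calls$motif)), " motif(s) called")
  })

  stage("ancestral", {
    if (is.null(joint_tree))
      joint_tree <- me_tree(distance_matrix(aln, config$correction))
    rooted <- NULL
    if (!is.null(config$outgroup)) {
      rooted <- root_tree(joint_tree, config$outgroup)
    } else {
      iso1 <- intersect(aln$ids, names(mapv)[mapv == "ISO1"])
      if (length(iso1) >= 1L && length(iso1) < length(aln$ids))
        rooted <- tryCatch(root_tree(joint_tree, iso1),
                           error = function(e) NULL)
    }
    if (is.null(rooted)) {
      # last resort: root on the lexicographically first leaf so the
      # reconstruction stage always produces output
      first_leaf <- sort(joint_tree$tip.label)[1]
      say("  isoform-1 set not monophyletic and no outgroup given; ",
          "rooting on leaf ", first_leaf)
      rooted <- root_tree(joint_tree, first_leaf)
    }
    model <- if (config$model_pi == "empirical")
      equal_input_model(aln = aln) else equal_input_model()
    recon <- marginal_posteriors(rooted, aln, model)
    write_ancestral_fasta(recon,
                          file.path(config$out_dir, "ancestors.fasta"),
                          file.path(config$out_dir, "ancestors.tsv"))
    say("  reconstructed ", length(recon$map), " ancestral sequences; ",
        "total log-likelihood ", format(sum(recon$site_loglik)))
  })

  say("pipeline complete")
  invisible(config$out_dir)
}
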