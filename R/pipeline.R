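# End-to-end orchestration: pair -> cluster -> score -> compare -> report.
# Every output is plain text (FASTA / TSV / JSON / SVG) and a manifest logs
# the seed and parameters, so a rerun with the same seed reproduces the
# score tables byte for byte.

#' Assemble a pipeline configuration
#'
#' Exactly one of `proteins` (homolog hit sets, see [build_paired_msa()])
#' or `msa_paths` (2-6 per-protein aligned FASTA files, see
#' [validate_user_paired_msas()]) must be given.
#'
#' @param out_dir Output directory.
#' @param proteins Named list for [build_paired_msa()].
#' @param msa_paths Character vector of per-protein FASTA paths (named;
#'   names become segment labels).
#' @param taxid_pattern Regex forwarded to [read_fasta_msa()].
#' @param methods Subset of `"mi"`, `"mfdca"`, `"plmdca"`, `"external"`.
#' @param external_scores Named character vector of score TSV paths
#'   (required when `"external"` is among the methods).
#' @param params Named list of per-method and display parameters; recognised
#'   entries (with defaults): `lambda` (0.05), `n_replicates` (100),
#'   `identity_threshold` (0.62), `theta` (0.8), `pseudocount_fraction`
#'   (0.5), `lambda_h` (0.01), `lambda_e` (NULL = 0.2 (L-1)),
#'   `min_fraction` (0.5), `overlap_n` (15), `circos_n` (100),
#'   `circos_class` ("both").
#' @param seed Integer seed driving every stochastic step.
#' @param max_total_length Guard on the summed reference length
#'   (default 2000).
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, proteins = NULL, msa_paths = NULL,
                       taxid_pattern = NULL, methods = "mi",
                       external_scores = NULL, params = list(), seed = 1,
                       max_total_length = 2000) {
  if (is.null(proteins) == is.null(msa_paths))
    stop("give exactly one of 'proteins' or 'msa_paths'")
  if (length(methods) == 0L) stop("at least one method must be selected")
  bad <- setdiff(methods, c("mi", "mfdca", "plmdca", "external"))
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if ("external" %in% methods && is.null(external_scores))
    stop("method 'external' needs 'external_scores'")
  defaults <- list(lambda = 0.05, n_replicates = 100,
                   identity_threshold = 0.62, theta = 0.8,
                   pseudocount_fraction = 0.5, lambda_h = 0.01,
                   lambda_e = NULL, min_fraction = 0.5, overlap_n = 15,
                   circos_n = 100, circos_class = "both")
  params <- utils::modifyList(defaults, params)
  structure(list(out_dir = out_dir, proteins = proteins,
                 msa_paths = msa_paths, taxid_pattern = taxid_pattern,
                 methods = methods, external_scores = external_scores,
                 params = params, seed = as.integer(seed),
                 max_total_length = max_total_length),
            class = "run_config")
}

#' Run the full covariation pipeline
#'
#' Builds (or validates) the paired alignment, reports Hobohm-1 clusters
#' and weights, scores every selected method, and writes score TSVs,
#' density summaries, the cross-method overlap, conservation track and
#' figures into `out_dir`, together with a JSON manifest of versions, seed
#' and parameters. On a stage failure the partial outputs are retained and
#' the manifest records the failure before the error propagates.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the `paired_msa`, per-method
#'   `score_table`s and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  manifest <- list(package = "intercov",
                   version = as.character(utils::packageVersion("intercov")),
                   r_version = R.version.string,
                   seed = config$seed,
                   methods = config$methods,
                   params = p[!vapply(p, is.null, logical(1L))],
                   status = "running", files = character(0))
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  emit <- function(name) manifest$files <<- c(manifest$files, name)
  run <- function() {
    pm <- if (!is.null(config$proteins))
      build_paired_msa(config$proteins, min_fraction = p$min_fraction,
                       max_total_length = config$max_total_length)
    else {
      msas <- lapply(config$msa_paths, read_fasta_msa,
                     taxid_pattern = config$taxid_pattern)
      names(msas) <- if (!is.null(names(config$msa_paths)))
        names(config$msa_paths) else paste0("protein", seq_along(msas))
      validate_user_paired_msas(msas, min_fraction = p$min_fraction)
    }
    write_paired_msa(pm, file.path(config$out_dir, "paired.fasta"),
                     file.path(config$out_dir, "segments.tsv"))
    emit("paired.fasta"); emit("segments.tsv")
    clusters <- hobohm1(pm, p$identity_threshold)
    cw <- cluster_weights(clusters)
    write_cluster_report(pm, clusters, cw,
                         file.path(config$out_dir, "clusters.tsv"))
    emit("clusters.tsv")
    freqs1 <- weighted_frequencies(pm, cw, lambda = p$lambda, pairs = FALSE)
    cons <- position_conservation(freqs1)
    write.table(data.frame(position = seq_along(cons), conservation = cons),
                file.path(config$out_dir, "conservation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("conservation.tsv")
    tables <- list()
    for (m in config$methods) {
      if (m == "mi") {
        sc <- mi_zscores(pm, weights = cw, lambda = p$lambda,
                         n_replicates = p$n_replicates, seed = config$seed)
        export_scores(pm, list(raw_mi = sc$raw_mi, mip = sc$mip,
                               zscore = sc$zscore),
                      file.path(config$out_dir, "mi.tsv"))
        emit("mi.tsv")
        tables$mi <- score_table(sc$zscore, pm$segments, "mi")
      } else if (m == "mfdca") {
        w2 <- reweight_sequences(pm, p$theta)
        model <- mfdca_fit(pm, w2, p$pseudocount_fraction)
        di <- direct_information(model)
        export_scores(pm, list(di = di),
                      file.path(config$out_dir, "mfdca.tsv"))
        emit("mfdca.tsv")
        tables$mfdca <- score_table(di, pm$segments, "mfdca")
      } else if (m == "plmdca") {
        w2 <- reweight_sequences(pm, p$theta)
        model <- plmdca_fit(pm, w2, lambda_h = p$lambda_h,
                            lambda_e = p$lambda_e)
        fr <- frobenius_apc_score(model)
        export_scores(pm, list(fnorm = fr$raw, fapc = fr$fapc),
                      file.path(config$out_dir, "plmdca.tsv"))
        emit("plmdca.tsv")
        tables$plmdca <- score_table(fr$fapc, pm$segments, "plmdca")
      } else if (m == "external") {
        for (nm in names(config$external_scores)) {
          tables[[nm]] <- import_external_scores(
            config$external_scores[[nm]], pm$segments, n_columns(pm),
            method = nm)
        }
      }
    }
    dens <- lapply(tables, function(tb) {
      d <- density_summary(tb)
      lapply(d[c("inter", "intra", "both")], function(cl)
        list(count = cl$count, mean = cl$mean, sd = cl$sd,
             quantiles = as.list(cl$quantiles)))
    })
    jsonlite::write_json(dens, file.path(config$out_dir, "density.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("density.json")
    ranked <- lapply(tables, rank_pairs)
    if (length(ranked) >= 2L) {
      n_inter <- sum(ranked[[1L]]$class == "inter")
      ov <- top_overlap(ranked[seq_len(min(4L, length(ranked)))], "inter",
                        min(p$overlap_n, n_inter))
      jsonlite::write_json(list(target_class = "inter",
                                n = min(p$overlap_n, n_inter),
                                overlap = ov$overlap, union = ov$union),
                           file.path(config$out_dir, "overlap.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      emit("overlap.json")
    }
    for (nm in names(tables)) {
      tb <- tables[[nm]]
      attr(tb, "reference_residues") <- pm$seqs[1L, ]
      n_avail <- sum(match_class(rank_pairs(tb)$class, p$circos_class))
      render_circos(tb, cons,
                    selection = list(class = p$circos_class,
                                     n = min(p$circos_n, n_avail)),
                    path = file.path(config$out_dir,
                                     paste0("circos_", nm, ".svg")))
      emit(paste0("circos_", nm, ".svg"))
      render_matrix(tb, file.path(config$out_dir,
                                  paste0("matrix_", nm, ".svg")))
      emit(paste0("matrix_", nm, ".svg"))
    }
    list(paired_msa = pm, tables = tables)
  }
  res <- tryCatch(run(), error = function(err) err)
  if (inherits(res, "error")) {
    manifest$status <- "failed"
    manifest$error <- conditionMessage(res)
    write_manifest()
    stop(res)
  }
  manifest$status <- "ok"
  write_manifest()
  invisible(c(res, list(manifest = manifest)))
}
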