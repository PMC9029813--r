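#' Configure an end-to-end screening pipeline
#'
#' @param data Either a path to a fingerprint CSV or a
#'   [synthetic_spec()] to generate one.
#' @param architectures List of [ae_architecture()]s to train; defaults
#'   to the three presets when the data are 1024-wide.
#' @param train A [train_config()] (its seed is overridden by `seed`).
#' @param screening A [screening_config()] (seed likewise overridden).
#' @param variant Similarity variant used on the encoded descriptors.
#' @param seed Global seed; every stage draws its own substream from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(data, architectures = NULL,
                            train = train_config(),
                            screening = screening_config(),
                            variant = "standard", seed = 1) {
  if (is.character(data) && !file.exists(data)) {
    stop("dataset file not found: ", data)
  }
  structure(list(data = data, architectures = architectures,
                 train = train, screening = screening,
                 variant = variant, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes: load or generate the dataset, min-max scale, train each
#' autoencoder architecture, encode, screen (binary-Tanimoto TAN
#' baseline on the raw binarized fingerprints plus continuous Tanimoto
#' on each encoded descriptor), write recall tables per cutoff, run the
#' Kendall concordance analysis on each table, and write a manifest
#' with the seed and a content hash of every artifact. Reruns with the
#' same config produce bit-identical files.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  t0 <- Sys.time()
  ds <- stage("load", {
    if (inherits(cfg$data, "synthetic_spec")) {
      spec <- cfg$data
      spec$seed <- derive_seed(cfg$seed, "synthetic")
      generate_dataset(spec)
    } else {
      read_fingerprints(cfg$data)
    }
  })
  message(sprintf("[load] %d molecules x %d features", nrow(ds$counts),
                  ncol(ds$counts)))
  scaled <- stage("scale", minmax_scale(ds))
  archs <- cfg$architectures %||% lapply(
    c("AE1-DR", "AE2-DR", "AE3-DR"), preset_architecture)
  methods <- list(TAN = list(dataset = binarize(ds), variant = "binary"))
  models <- list()
  for (arch in archs) {
    tcfg <- cfg$train
    tcfg$seed <- derive_seed(cfg$seed, paste0("train:", arch$name))
    fit <- stage(paste0("train:", arch$name),
                 train_autoencoder(scaled, arch, tcfg))
    message(sprintf("[train:%s] %d epochs, final loss %.5f (%s)", arch$name,
                    fit$report$epochs, tail(fit$report$loss, 1),
                    fit$report$stopped_by))
    models[[arch$name]] <- fit
    save_ae_model(fit$model, file.path(out_dir,
                                       paste0("model_", arch$name, ".rds")))
    enc <- stage(paste0("encode:", arch$name),
                 encode_dataset(fit$model, scaled))
    methods[[arch$name]] <- list(dataset = enc, variant = cfg$variant)
  }
  scfg <- cfg$screening
  scfg$seed <- derive_seed(cfg$seed, "references")
  tables <- stage("screen", run_benchmark(methods, scfg))
  outputs <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, sprintf("recall_top%s.csv", sub("%", "", nm)))
    write_recall_table(tables[[nm]], p)
    outputs <- c(outputs, p)
    kres <- stage("kendall", kendall_w(tables[[nm]]$recalls))
    kp <- file.path(out_dir, sprintf("kendall_top%s.json", sub("%", "", nm)))
    jsonlite::write_json(
      list(W = kres$W, S = kres$S, chi_sq = kres$chi_sq, df = kres$df,
           p = kres$p, mean_ranks = as.list(kres$mean_ranks)),
      kp, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, kp)
    message(sprintf("[kendall %s] W = %.3f, p = %.3g, mean recall: %s", nm,
                    kres$W, kres$p,
                    paste(sprintf("%s=%.1f", names(tables[[nm]]$mean_row),
                                  tables[[nm]]$mean_row), collapse = " ")))
  }
  outputs <- c(outputs, file.path(out_dir,
                                  paste0("model_", names(models), ".rds")))
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("aescreen")),
    n_molecules = length(ds$ids),
    feature_dim = ds$feature_dim,
    architectures = vapply(archs, `[[`, character(1), "name"),
    files = lapply(sort(outputs), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[done] %d artifacts in %s (%.1fs)",
                  length(outputs) + 1, out_dir,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(manifest)
}

#' Verify a pipeline output directory against its manifest
#'
#' Re-hashes every file listed in `manifest.json` and checks the
#' recorded MD5 sums.
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @return `TRUE` if all hashes match; otherwise an error naming the
#'   first mismatching file.
#' @export
verify_manifest <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  for (f in mf$files) {
    p <- file.path(out_dir, f$path)
    if (!file.exists(p)) stop("missing artifact: ", f$path)
    if (!identical(unname(tools::md5sum(p)), f$md5)) {
      stop("hash mismatch for ", f$path)
    }
  }
  TRUE
}
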