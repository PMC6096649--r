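# Plain-text array container for cohorts.
#
# Layout: <dir>/manifest.json holds cohort-level metadata (groups,
# conditions, channels, sampling rate, epoch counts, seeds); each subject
# gets one tab-separated file <dir>/<id>.tsv with columns
#   condition  channel  epoch  s1 ... sN
# one row per epoch, samples in acquisition order. Everything is text, so
# cohorts round-trip across languages.

#' Write a cohort to the plain-text array container
#'
#' @param cohort A `cfc_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cfc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- cohort$subjects[[1]]$data[[1]][[1]][[1]]$sampling_rate
  manifest <- list(
    format = "crossfreq-cohort/1",
    sampling_rate = fs,
    conditions = cohort$conditions,
    channels = cohort$channels,
    groups = cohort$groups,
    subjects = lapply(cohort$subjects, function(s) {
      list(id = s$id, group = s$group)
    }),
    n_epochs = length(cohort$subjects[[1]]$data[[1]][[1]]),
    master_seed = cohort$provenance$master_seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(cohort$covariates)) {
    utils::write.table(cohort$covariates,
                       file.path(dir, "covariates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (s in cohort$subjects) {
    rows <- list()
    for (cond in cohort$conditions) {
      for (ch in cohort$channels) {
        for (ep in s$data[[cond]][[ch]]) {
          rows[[length(rows) + 1L]] <- c(cond, ch, ep$index,
                                         format(ep$samples, digits = 10))
        }
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- c("condition", "channel", "epoch",
                     paste0("s", seq_len(ncol(m) - 3L)))
    utils::write.table(m, file.path(dir, paste0(s$id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort from the plain-text array container
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `cfc_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "crossfreq-cohort/1")) {
    stop("not a crossfreq cohort container", call. = FALSE)
  }
  fs <- manifest$sampling_rate
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    id <- manifest$subjects$id[i]
    tab <- utils::read.table(file.path(dir, paste0(id, ".tsv")),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    data <- list()
    for (cond in manifest$conditions) {
      data[[cond]] <- list()
      for (ch in manifest$channels) {
        sel <- tab$condition == cond & tab$channel == ch
        sub <- tab[sel, , drop = FALSE]
        data[[cond]][[ch]] <- lapply(seq_len(nrow(sub)), function(j) {
          epoch(as.numeric(sub[j, -(1:3)]), fs, channel = ch,
                condition = cond, index = as.integer(sub$epoch[j]))
        })
      }
    }
    list(id = id, group = manifest$subjects$group[i], pac_depth = NA_real_,
         data = data)
  })
  cov_path <- file.path(dir, "covariates.tsv")
  covariates <- if (file.exists(cov_path)) {
    utils::read.table(cov_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  structure(
    list(subjects = subjects, conditions = manifest$conditions,
         channels = manifest$channels, groups = manifest$groups,
         covariates = covariates,
         provenance = list(master_seed = manifest$master_seed,
                           source = dir)),
    class = "cfc_cohort"
  )
}
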