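## Plain-text interchange formats between the pipeline stages.  Every
## stage communicates through these files only.

#' Write a generated trace series to CSV files plus a manifest
#'
#' One `time_s,signal` CSV per trace and a manifest mapping file to
#' concentrations and variant labels.
#'
#' @param series Output of [gen_trace_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the manifest CSV.
#' @export
write_trace_series <- function(series, dir, prefix = "trace") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- series$manifest
  man$file <- sprintf("%s_%03d.csv", prefix, man$trace)
  for (i in seq_along(series$traces))
    write.csv(as.data.frame(series$traces[[i]]),
              file.path(dir, man$file[i]), row.names = FALSE)
  path <- file.path(dir, paste0(prefix, "_manifest.csv"))
  write.csv(man[, c("file", "ligand_conc_uM", "probe_conc_uM",
                    "variant_receptor", "variant_ligand")],
            path, row.names = FALSE)
  path
}

#' Read a trace manifest and its trace CSVs
#'
#' @param manifest_path Manifest CSV (columns `file`,
#'   `ligand_conc_uM`, `probe_conc_uM`, and variant labels).
#' @return List of [binding_trace()] objects with variant labels as
#'   attributes.
#' @export
read_trace_manifest <- function(manifest_path) {
  man <- read.csv(manifest_path)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    d <- read.csv(file.path(dir, man$file[i]))
    tr <- suppressWarnings(binding_trace(d$time_s, d$signal,
                                         man$ligand_conc_uM[i],
                                         man$probe_conc_uM[i]))
    attr(tr, "variant_receptor") <- man$variant_receptor[i]
    attr(tr, "variant_ligand") <- man$variant_ligand[i]
    tr
  })
}

#' Write a rate-constant table
#'
#' The canonical exchange format between the kinetics and energetics
#' stages: `receptor_variant,ligand_variant,kon_uM_s,kon_sd,koff_s,
#' koff_sd,temperature_K`.
#'
#' @param rates List of [rate_constants()] objects.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(rates, path) {
  df <- do.call(rbind, lapply(rates, function(r)
    data.frame(receptor_variant = r$variant_receptor,
               ligand_variant = r$variant_ligand,
               kon_uM_s = r$k_on, kon_sd = r$k_on_sd,
               koff_s = r$k_off, koff_sd = r$k_off_sd,
               temperature_K = r$temperature)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a rate-constant table
#'
#' @param path CSV in the [write_rates_csv()] format.
#' @return List of [rate_constants()] objects.
#' @export
read_rates_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    suppressWarnings(rate_constants(
      df$kon_uM_s[i], df$koff_s[i], df$kon_sd[i], df$koff_sd[i],
      temperature = df$temperature_K[i],
      variant_receptor = df$receptor_variant[i],
      variant_ligand = df$ligand_variant[i])))
}

#' Read a Phi-restraint CSV (`chain,residue,phi,phi_sd`)
#'
#' @param path CSV path.
#' @param ref Optional [native_contacts()] map for validation.
#' @return A [phi_restraint_set()].
#' @export
read_restraints_csv <- function(path, ref = NULL) {
  df <- read.csv(path)
  names(df)[names(df) == "residue"] <- "resid"
  phi_restraint_set(df$chain, df$resid, df$phi,
                    if ("phi_sd" %in% names(df)) df$phi_sd else NA_real_,
                    ref = ref)
}

#' Write a Phi-restraint CSV
#'
#' @param restraints A [phi_restraint_set()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_restraints_csv <- function(restraints, path) {
  df <- data.frame(chain = restraints$chain, residue = restraints$resid,
                   phi = restraints$phi, phi_sd = restraints$phi_sd)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a contact (or contact-frequency) map as CSV
#'
#' @param map A [native_contacts()] map or a `$native` frequency
#'   table.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
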