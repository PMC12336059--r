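#' Write / read a BOLD study as NIfTI-1
#'
#' The 4D series is written with voxel sizes and TR in the header; the
#' protocol is not stored in the file and must be supplied on read.
#'
#' @param study A [bold_study()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param protocol Protocol to attach on read.
#' @return `write_bold_nifti`: the path, invisibly; `read_bold_nifti`: a
#'   [bold_study()].
#' @export
write_bold_nifti <- function(study, path) {
  img <- RNifti::asNifti(study$data)
  RNifti::pixdim(img) <- c(study$voxdim, study$tr)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path, protocol = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  bold_study(unclass(img)[, , , , drop = FALSE], tr = pd[4],
             protocol = protocol, voxdim = pd[1:3])
}

#' Write / read a phase-contrast scan as NIfTI-1
#'
#' Velocity and complex-difference magnitude go to `<prefix>_vel.nii.gz`
#' and `<prefix>_cd.nii.gz`; venc, voxel area and the acquisition window
#' are stored in a `<prefix>_meta.csv` sidecar.
#'
#' @param scan A [pc_scan()].
#' @param prefix Output path prefix.
#' @return `write_pc_nifti`: the prefix, invisibly; `read_pc_nifti`: a
#'   [pc_scan()].
#' @export
write_pc_nifti <- function(scan, prefix) {
  vox <- sqrt(scan$voxel_area)
  vel <- RNifti::asNifti(scan$velocity)
  RNifti::pixdim(vel) <- c(vox, vox)
  RNifti::writeNifti(vel, paste0(prefix, "_vel.nii.gz"), datatype = "double")
  cd <- RNifti::asNifti(scan$cd_magnitude)
  RNifti::pixdim(cd) <- c(vox, vox)
  RNifti::writeNifti(cd, paste0(prefix, "_cd.nii.gz"), datatype = "double")
  utils::write.csv(data.frame(venc = scan$venc, voxel_area = scan$voxel_area,
                              window_start = scan$window[1],
                              window_end = scan$window[2]),
                   paste0(prefix, "_meta.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_pc_nifti
#' @export
read_pc_nifti <- function(prefix) {
  vel <- as.matrix(RNifti::readNifti(paste0(prefix, "_vel.nii.gz")))
  cd <- as.matrix(RNifti::readNifti(paste0(prefix, "_cd.nii.gz")))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  pc_scan(vel, cd, venc = meta$venc, voxel_area = meta$voxel_area,
          window = c(meta$window_start, meta$window_end))
}

#' Write a logical mask as NIfTI-1
#' @param mask Logical matrix or 3D array.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param path NIfTI path of a 0/1 mask.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(unclass(img) > 0.5, dim(img))
}

#' Render a simulated cohort to disk
#'
#' Writes, for every subject and state, the raw inputs the pipeline
#' consumes -- capnograph CSVs, BOLD 4D NIfTI, PC velocity/magnitude
#' NIfTI pairs with sinus-mask NIfTI, TRUST volumes as NIfTI with an
#' eTE/pair manifest CSV -- plus a cohort `manifest.csv` of subject
#' metadata (group, sex, age, brain volume) and a `ground_truth.csv` for
#' recovery checks.
#'
#' @param cohort A [generate_cohort()] table.
#' @param dir Output directory (created if needed).
#' @param states Which states to render.
#' @param modalities Which modalities to render.
#' @param calib A [trust_calibration()].
#' @param seed Integer seed (matches [run_cohort_pipeline()] seeding).
#' @return The directory, invisibly.
#' @export
simulate_cohort_dir <- function(cohort, dir, states = c("pre", "post"),
                                modalities = c("pc", "bold", "trust"),
                                calib = trust_calibration(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort[, c("subject_id", "group", "sex", "age", "bvol")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    for (st in states) {
      sdir <- file.path(dir, subj$subject_id, st)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      sseed <- seed + 100000L * i + 1000L * (st == "post")
      if ("pc" %in% modalities) {
        inp <- render_pc_inputs(subj, st, seed = sseed)
        write_capno(inp$trace, file.path(sdir, "capno_pc.csv"))
        write_pc_nifti(inp$pair$ra, file.path(sdir, "pc_ra"))
        write_pc_nifti(inp$pair$hc, file.path(sdir, "pc_hc"))
        write_mask_nifti(inp$pair$roi, file.path(sdir, "sss_roi.nii.gz"))
      }
      if ("bold" %in% modalities) {
        inp <- render_bold_inputs(subj, st, seed = sseed + 1L)
        write_capno(inp$trace, file.path(sdir, "capno_bold.csv"))
        write_bold_nifti(inp$study, file.path(sdir, "bold.nii.gz"))
      }
      if ("trust" %in% modalities) {
        inp <- render_trust_inputs(subj, st, calib = calib, seed = sseed + 2L)
        manifest <- list()
        for (j in seq_along(inp$series$etes)) {
          for (p in seq_along(inp$series$volumes[[j]])) {
            pr <- inp$series$volumes[[j]][[p]]
            lab <- sprintf("trust_ete%03d_pair%d_label.nii.gz",
                           inp$series$etes[j], p)
            ctl <- sub("label", "control", lab)
            RNifti::writeNifti(RNifti::asNifti(pr$label), file.path(sdir, lab),
                               datatype = "double")
            RNifti::writeNifti(RNifti::asNifti(pr$control),
                               file.path(sdir, ctl), datatype = "double")
            manifest[[length(manifest) + 1L]] <-
              data.frame(ete = inp$series$etes[j], pair = p,
                         label = lab, control = ctl)
          }
        }
        utils::write.csv(do.call(rbind, manifest),
                         file.path(sdir, "trust_manifest.csv"), row.names = FALSE)
        write_mask_nifti(inp$series$roi, file.path(sdir, "trust_roi.nii.gz"))
      }
    }
  }
  invisible(dir)
}

#' Read a TRUST series rendered by [simulate_cohort_dir()]
#'
#' @param dir Subject/state directory containing `trust_manifest.csv`.
#' @return A TRUST series list (`volumes`, `etes`, `roi`).
#' @export
read_trust_series <- function(dir) {
  man <- utils::read.csv(file.path(dir, "trust_manifest.csv"))
  etes <- sort(unique(man$ete))
  volumes <- lapply(etes, function(e) {
    sub <- man[man$ete == e, ]
    lapply(seq_len(nrow(sub)), function(r)
      list(label = as.matrix(RNifti::readNifti(file.path(dir, sub$label[r]))),
           control = as.matrix(RNifti::readNifti(file.path(dir, sub$control[r])))))
  })
  list(volumes = volumes, etes = etes,
       roi = read_mask_nifti(file.path(dir, "trust_roi.nii.gz")))
}
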