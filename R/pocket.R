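# Binding-pocket hydration: first-shell voxels attributed to residues
# by nearest-atom (Voronoi-style) assignment.

#' Define a pocket by its residues
#'
#' @param name Pocket label.
#' @param resno Integer vector of residue numbers.
#' @param resid Optional character vector of residue names (same
#'   length), checked against the solute when counting.
#' @return Object of class `pocket_spec`.
#' @export
pocket_spec <- function(name, resno, resid = NULL) {
  resno <- as.integer(resno)
  if (!length(resno)) stop("a pocket needs at least one residue")
  if (!is.null(resid) && length(resid) != length(resno))
    stop("resid and resno lengths differ")
  structure(list(name = name, resno = resno, resid = resid),
            class = "pocket_spec")
}

#' Sudlow drug-binding sites of serum albumin
#'
#' The two high-affinity binding pockets of human serum albumin
#' (subdomain IIA = site I, subdomain IIIA = site II) as residue lists,
#' read from the shipped pocket catalogue.
#'
#' @param file Optional alternative YAML pocket file.
#' @return Named list of [pocket_spec()] objects.
#' @export
sudlow_sites <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pockets.yaml", package = "rismhydra",
                        mustWork = TRUE)
  y <- yaml::read_yaml(file)
  out <- lapply(names(y), function(nm) {
    rr <- do.call(rbind, lapply(y[[nm]]$residues, function(e)
      data.frame(resid = e$resid, resno = e$resno)))
    pocket_spec(nm, rr$resno, rr$resid)
  })
  names(out) <- names(y)
  out
}

#' Water count in a pocket region
#'
#' First-shell voxels (`d <= r_cut`) are attributed to their nearest
#' solute residue; the pocket count is the density-weighted integral of
#' g_Ow over voxels attributed to pocket residues.  Counts over a full
#' residue partition sum exactly to the total hydration number.
#'
#' @param g_Ow Distribution array.
#' @param dist A [distance_transform()] result (carries nearest-atom
#'   indices).
#' @param solute A [solute_system()].
#' @param pocket A [pocket_spec()].
#' @param r_cut Shell boundary, A.
#' @param rho Bulk oxygen density, 1/A^3.
#' @return Expected water count in the pocket region.
#' @export
pocket_hydration <- function(g_Ow, dist, solute, pocket, r_cut, rho) {
  a <- solute$atoms
  missing_res <- setdiff(pocket$resno, a$resno)
  if (length(missing_res))
    stop(sprintf("pocket '%s' residue(s) absent from solute: %s",
                 pocket$name, paste(missing_res, collapse = ", ")))
  if (!is.null(pocket$resid)) {
    got <- a$resid[match(pocket$resno, a$resno)]
    bad <- which(got != pocket$resid)
    if (length(bad))
      stop(sprintf("pocket '%s': residue %d is %s in the solute, expected %s",
                   pocket$name, pocket$resno[bad[1]], got[bad[1]],
                   pocket$resid[bad[1]]))
  }
  shell <- dist$d <= r_cut
  vox_res <- a$resno[dist$nearest[shell]]
  sum(g_Ow[shell][vox_res %in% pocket$resno]) * dist$grid$dv * rho
}
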