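#' Molecular topology
#'
#' A light-weight description of the atoms shared by every frame of a
#' trajectory ensemble: chain, residue number, residue name, atom name and
#' element for each atom.  From these the constructor derives the sets that
#' the hydrogen-bond and annotation machinery needs: the backbone amide sites
#' (residues carrying an N--H), the protein hydrogen-bond acceptor atoms
#' (protein O and N), and the water oxygens.
#'
#' Water is recognized by residue name (`HOH`, `WAT`, `SOL`, `TIP3`, `SPC`).
#' The amide hydrogen is the atom named `H` or `HN` in a residue that also has
#' a backbone `N`.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`, `name`,
#'   and optionally `elem` (inferred from the first letter of `name` when
#'   absent).  One row per atom, in trajectory atom order.
#' @return An object of class `"topology"`: the atom table plus derived index
#'   vectors `amide_sites` (data frame: `site`, `chain`, `resno`, `n_idx`,
#'   `h_idx`), `acceptor_idx`, `water_o_idx` and `ca_idx`.
#' @examples
#' top <- topology(data.frame(
#'   chain = "A", resno = c(1, 1, 1, 1, 1),
#'   resname = "GLY", name = c("N", "H", "CA", "C", "O")))
#' top$amide_sites$site
#' @export
topology <- function(atoms) {
  need <- c("chain", "resno", "resname", "name")
  if (!all(need %in% names(atoms)))
    stop2("atoms must have columns ", paste(need, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- as.character(atoms$resname)
  atoms$name <- as.character(atoms$name)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$elem))
    atoms$elem <- substr(atoms$name, 1L, 1L)
  atoms$elem <- toupper(as.character(atoms$elem))

  water_res <- c("HOH", "WAT", "SOL", "TIP3", "SPC")
  is_water <- atoms$resname %in% water_res
  atoms$is_water <- is_water

  # residue numbers must be unique within a chain (per residue, not per atom)
  resdf <- unique(atoms[!is_water, c("chain", "resno")])
  key <- paste(resdf$chain, resdf$resno)
  if (anyDuplicated(key))
    stop2("duplicated residue index within a chain: ",
          paste(unique(key[duplicated(key)]), collapse = ", "))

  idx <- seq_len(nrow(atoms))
  prot <- !is_water

  # backbone amide sites: one N and one attached H per residue
  amide <- NULL
  for (k in key) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1L]]
    ch <- parts[1L]; rn <- as.integer(parts[2L])
    in_res <- prot & atoms$chain == ch & atoms$resno == rn
    n_i <- idx[in_res & atoms$name == "N"]
    h_i <- idx[in_res & atoms$name %in% c("H", "HN")]
    if (length(n_i) == 1L && length(h_i) >= 1L) {
      if (length(h_i) > 1L)
        stop2("site ", site_label(ch, rn), " has ", length(h_i),
              " amide hydrogens; expected one")
      amide <- rbind(amide, data.frame(
        site = site_label(ch, rn), chain = ch, resno = rn,
        n_idx = n_i, h_idx = h_i, stringsAsFactors = FALSE))
    }
  }

  out <- list(
    atoms = atoms,
    amide_sites = amide %||% data.frame(site = character(), chain = character(),
                                        resno = integer(), n_idx = integer(),
                                        h_idx = integer()),
    acceptor_idx = idx[prot & atoms$elem %in% c("O", "N")],
    water_o_idx = idx[is_water & atoms$elem == "O"],
    ca_idx = idx[prot & atoms$name == "CA"],
    n_atoms = nrow(atoms)
  )
  class(out) <- "topology"
  out
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      nrow(x$amide_sites), "amide sites,",
      length(x$acceptor_idx), "protein acceptors,",
      length(x$water_o_idx), "water oxygens\n")
  invisible(x)
}

# Index of one named atom; error names the residue when absent.
atom_index <- function(top, chain, resno, name) {
  a <- top$atoms
  i <- which(!a$is_water & a$chain == chain & a$resno == resno & a$name == name)
  if (length(i) != 1L)
    stop2("atom ", name, " of residue ", site_label(chain, resno),
          if (length(i) == 0L) " not found in topology" else " is not unique")
  i
}

# Indices of the Cα atoms for a (chain, resno) selection, in selection order.
ca_indices <- function(top, chain, resno) {
  mapply(function(ch, rn) atom_index(top, ch, rn, "CA"), chain, resno,
         USE.NAMES = FALSE)
}
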