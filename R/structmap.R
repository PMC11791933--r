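# Contact-map featurization: C-alpha distances -> 3-channel clipped
# similarity in [0,1]. value = (d - min(C, d)) / d with threshold d per
# channel (default 22 A for all three channels).

aa3to1 <- function(resid3) {
  one <- suppressWarnings(bio3d::aa321(resid3))
  one[is.na(one) | !(one %in% c(.AA20, "X"))] <- "X"
  one
}

#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' Extracts one coordinate triple per residue with a C-alpha atom, in residue
#' order, for one chain. Residues lacking a C-alpha are dropped with a
#' warning, and the returned sequence covers the retained residues only.
#' Alternate-location duplicates are resolved by highest occupancy, ties by
#' altloc `A` (then first occurrence).
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier; default is the first chain in the file.
#' @param id Record id; defaults to the file base name.
#' @return A [protein_record()] with `coords` set.
#' @export
read_calpha_coords <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("read_calpha_coords: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  # keep altloc duplicates; they are resolved below by occupancy
  struct <- if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE)
            else bio3d::read.pdb(path, rm.alt = FALSE)
  at <- struct$atom
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("read_calpha_coords: chain '", chain, "' not found; available: ",
         paste(chains, collapse = ", "))
  ca <- at[at$chain == chain & at$elety == "CA" &
             (is.na(at$type) | at$type == "ATOM"), , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("read_calpha_coords: no C-alpha atoms in chain '", chain, "'")
  # residue key preserving file order
  ins <- if ("insert" %in% names(ca)) ifelse(is.na(ca$insert), "", ca$insert) else ""
  key <- paste(ca$resno, ins, sep = "_")
  occ <- if ("o" %in% names(ca)) ifelse(is.na(ca$o), 1, ca$o) else rep(1, nrow(ca))
  alt <- if ("alt" %in% names(ca)) ifelse(is.na(ca$alt), "", ca$alt) else rep("", nrow(ca))
  keep <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      best <- idx[occ[idx] == max(occ[idx])]
      if (length(best) > 1L) {
        a <- best[alt[best] %in% c("A", "")]
        best <- if (length(a) > 0L) a[1] else best[1]
      }
      keep <- c(keep, best[1])
    } else keep <- c(keep, idx)
  }
  keep <- sort(keep)
  ca <- ca[keep, , drop = FALSE]
  # warn about residues present in the chain but lacking a C-alpha
  n_res <- length(unique(at$resno[at$chain == chain &
                                    (is.na(at$type) | at$type == "ATOM")]))
  if (n_res > nrow(ca))
    warning("read_calpha_coords: ", n_res - nrow(ca),
            " residue(s) without a C-alpha atom dropped")
  coords <- cbind(x = ca$x, y = ca$y, z = ca$z)
  seq1 <- paste(aa3to1(ca$resid), collapse = "")
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  protein_record(id = id, sequence = seq1, coords = coords)
}

#' Read C-alpha coordinates from a plain table
#'
#' Reads a whitespace- or tab-separated table with columns
#' `index, x, y, z` (header optional) as written by [write_corpus()].
#'
#' @param path Table path.
#' @param sequence Sequence string for the record (same length as the table).
#' @param id Record id; defaults to the file base name.
#' @param family Optional family label.
#' @return A [protein_record()].
#' @export
read_coord_table <- function(path, sequence, id = NULL, family = NULL) {
  tab <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("x", "y", "z") %in% names(tab)))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  protein_record(id = id, sequence = sequence,
                 coords = as.matrix(tab[, c("x", "y", "z")]), family = family)
}

#' Pairwise C-alpha distance matrix
#'
#' @param coords Numeric matrix, one (x, y, z) row per residue, in Angstrom.
#' @return Symmetric L x L Euclidean distance matrix with zero diagonal.
#' @export
distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("distance_matrix: need at least one coordinate")
  if (!all(is.finite(coords))) stop("distance_matrix: non-finite coordinate")
  as.matrix(stats::dist(coords))
}

#' Clipped-similarity contact-map tensor
#'
#' Transforms a raw C-alpha distance matrix `C` into a bounded similarity,
#' per channel: `(d - CLIP(C, d)) / d`, where `CLIP` replaces distances above
#' the threshold `d` by `d`. Values lie in `[0, 1]`: 1 at zero distance
#' (diagonal), 0 at or beyond the threshold. The default threshold is 22
#' Angstrom for all three channels; per-channel thresholds are configurable.
#'
#' @param dist L x L distance matrix from [distance_matrix()].
#' @param d Distance threshold(s) in Angstrom: scalar (recycled over the 3
#'   channels) or length-3 vector. Must be positive.
#' @param max_len Residue truncation limit; the map is truncated to its first
#'   `max_len` rows/columns (mirroring sequence truncation). Default 512.
#' @return A `contact_map`: list with `values` (3 x L x L array), `length`,
#'   and `thresholds`.
#' @export
featurize <- function(dist, d = 22, max_len = 512L) {
  dist <- as.matrix(dist)
  if (any(d <= 0)) stop("featurize: threshold d must be positive")
  if (length(d) == 1L) d <- rep(d, 3L)
  stopifnot(length(d) == 3L)
  L <- min(nrow(dist), max_len)
  dist <- dist[seq_len(L), seq_len(L), drop = FALSE]
  vals <- array(0, dim = c(3L, L, L))
  for (ch in 1:3) vals[ch, , ] <- (d[ch] - pmin(dist, d[ch])) / d[ch]
  structure(list(values = vals, length = L, thresholds = d),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> 3 x ", x$length, " x ", x$length,
      ", thresholds ", paste(x$thresholds, collapse = "/"), " A\n", sep = "")
  invisible(x)
}

#' Resize a contact map to the structure encoder's input resolution
#'
#' Maps of side `L <= side` are zero-padded bottom/right (padding value 0 =
#' "no contact") with a patch-coverage mask marking patches that overlap real
#' rows/columns; maps with `L > side` are bilinearly downscaled to
#' `side x side` with a full-coverage mask. Masked-out patches are excluded
#' from pooling by the structure encoder.
#'
#' @param map A `contact_map` from [featurize()].
#' @param side Encoder input resolution (pixels per side); must be divisible
#'   by `patch_size`.
#' @param patch_size Patch size of the structure encoder.
#' @return A `struct_input`: list with `values` (3 x side x side array),
#'   `patch_mask` (P x P logical, P = side / patch_size), `length`, `side`,
#'   `patch_size`.
#' @export
resize_for_encoder <- function(map, side, patch_size = 8L) {
  stopifnot(inherits(map, "contact_map"))
  if (side %% patch_size != 0L)
    stop("resize_for_encoder: side must be divisible by patch_size")
  L <- map$length
  P <- side %/% patch_size
  out <- array(0, dim = c(3L, side, side))
  if (L <= side) {
    out[, seq_len(L), seq_len(L)] <- map$values
    pcover <- ceiling(L / patch_size)           # patches overlapping content
    patch_mask <- matrix(FALSE, P, P)
    patch_mask[seq_len(pcover), seq_len(pcover)] <- TRUE
  } else {
    for (ch in 1:3)
      out[ch, , ] <- EBImage::resize(map$values[ch, , ], w = side, h = side)
    patch_mask <- matrix(TRUE, P, P)
  }
  structure(list(values = out, patch_mask = patch_mask, length = L,
                 side = side, patch_size = patch_size),
            class = "struct_input")
}

#' Cache contact-map tensors for a corpus
#'
#' Featurizes every record's coordinates and stores the resulting tensors in
#' a single RDS archive keyed by protein id (a run-time cache; regenerate
#' rather than ship it).
#'
#' @param records List of [protein_record()] with coords.
#' @param path Output `.rds` path.
#' @param d,max_len Passed to [featurize()].
#' @return `path`, invisibly.
#' @export
cache_contact_maps <- function(records, path, d = 22, max_len = 512L) {
  maps <- lapply(records, function(r) {
    if (is.null(r$coords)) stop("cache_contact_maps: record ", r$id,
                                " has no coordinates")
    featurize(distance_matrix(r$coords), d = d, max_len = max_len)
  })
  names(maps) <- vapply(records, `[[`, "", "id")
  saveRDS(maps, path)
  invisible(path)
}
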