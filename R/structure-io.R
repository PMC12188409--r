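## Structure and trajectory I/O.  PDB parsing and writing are delegated to
## bio3d; this module adds the package's bookkeeping contracts on top:
## deterministic atom ordering, altloc policy, chain-role mapping, strict
## residue-selection errors and fixed-width checks on output.

#' Map chains to functional roles
#'
#' F1-type entries label chains inconsistently, so roles are assigned from
#' residue counts: among the six largest protein chains the three larger are
#' `alpha` and the three smaller `beta` (alpha chains are consistently
#' longer); the largest remaining chain with at least 150 residues is
#' `gamma`; chains of 8-60 residues are flagged `inhibitor`; everything else
#' is `other`.  The heuristic cannot distinguish a short inhibitor chain
#' from a small intrinsic subunit of similar length, so an explicit
#' user-supplied map always takes precedence.
#'
#' @param model a [StructureModel-class].
#' @return named character vector chain id -> role.
#' @export
chainRoleMap <- function(model) {
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  if (!nrow(a)) return(character(0))
  counts <- vapply(split(a$resno, a$chain),
                   function(r) length(unique(r)), integer(1))
  roles <- setNames(rep("other", length(counts)), names(counts))
  big <- names(sort(counts[counts >= 100], decreasing = TRUE))
  if (length(big) >= 6L) {
    roles[big[1:3]] <- "alpha"
    roles[big[4:6]] <- "beta"
    rest <- big[-(1:6)]
  } else rest <- big
  gcand <- rest[counts[rest] >= 150]
  if (length(gcand)) roles[gcand[1]] <- "gamma"
  roles[counts >= 8 & counts <= 60] <- "inhibitor"
  roles
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records (waters and heteroatoms are retained but
#' flagged in the `het` column).  Alternate locations keep altloc 'A' or
#' blank, breaking ties by highest occupancy.  Atoms are returned in
#' ascending (chain, residue, atom name) order; multi-model files are
#' returned as a [Trajectory-class] when `modelPolicy = "all"`.
#'
#' @param path PDB file path.
#' @param modelPolicy `"first"` (default) or `"all"`.
#' @param roleMap optional named character vector chain id -> role,
#'   overriding [chainRoleMap()] auto-detection.
#' @return A [StructureModel-class], or a [Trajectory-class] for
#'   `modelPolicy = "all"` on multi-model input (frame times default to the
#'   model index in ns).
#' @export
readPDB <- function(path, modelPolicy = c("first", "all"), roleMap = NULL) {
  modelPolicy <- match.arg(modelPolicy)
  if (!file.exists(path)) stop("no such file: ", path)
  p <- tryCatch(
    bio3d::read.pdb(path, multi = (modelPolicy == "all"), verbose = FALSE),
    error = function(e) stop("unreadable PDB record in '", path, "'",
                             badRecordLine(path), ": ",
                             conditionMessage(e), call. = FALSE))
  at <- p$atom
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    stop("unreadable coordinate field in '", path, "'",
         badRecordLine(path), call. = FALSE)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  ## altloc tie-break: highest occupancy among surviving duplicates
  at <- at[keep, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$elety)
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    at <- at[order(key, -occ), , drop = FALSE]
    dup <- duplicated(paste(at$chain, at$resno, at$elety))
    at <- at[!dup, , drop = FALSE]
  }
  idx <- as.integer(rownames(at))   # row positions in the original table
  idx <- match(rownames(at), rownames(p$atom))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    resname = at$resid,
    elety = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1L, 1L), trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  ord <- order(atoms$chain, atoms$resno, atoms$elety)
  atoms <- atoms[ord, , drop = FALSE]
  nmodels <- if (is.matrix(p$xyz)) nrow(p$xyz) else 1L
  if (modelPolicy == "all" && nmodels > 1L) {
    cols <- as.vector(t(cbind(3L * (idx - 1L) + 1L,
                              3L * (idx - 1L) + 2L,
                              3L * (idx - 1L) + 3L)))
    xyz <- p$xyz[, cols, drop = FALSE]
    percols <- as.vector(t(cbind(3L * (ord - 1L) + 1L,
                                 3L * (ord - 1L) + 2L,
                                 3L * (ord - 1L) + 3L)))
    xyz <- xyz[, percols, drop = FALSE]
    topo <- StructureModel(atoms, title = basename(path), roleMap = roleMap)
    ## constructor re-sorts; atoms already in final order so layout matches
    return(new("Trajectory", topology = topo, xyz = unname(xyz),
               times = seq_len(nmodels) - 1,
               metadata = data.frame()))
  }
  StructureModel(atoms, title = basename(path), roleMap = roleMap)
}

## locate the first ATOM/HETATM line whose coordinate fields do not parse,
## for error messages with a line number
badRecordLine <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) return(paste0(" (line ", i, ")"))
  }
  ""
}

#' Select atoms by role and residue ranges
#'
#' Applies one or more [Selection-class] objects to a structure.  Atoms are
#' returned in ascending (chain, residue, atom name) order within each
#' selection, selections concatenated in the order given.  Any requested
#' residue missing the requested atoms is an error naming every gap; with
#' `partner` residues (see `restrict`) the selection can be restricted to a
#' batch-wide intersection first.
#'
#' @param model a [StructureModel-class].
#' @param sel a [Selection-class] or list of them.
#' @param chain optional chain id(s) to use instead of every chain carrying
#'   the selection's role.
#' @param restrict optional integer vector of residue numbers to intersect
#'   the ranges with (batch "intersect" mode, see [commonResidues()]).
#' @return list with `coords` (n x 3 matrix, Angstrom) and `labels`
#'   (data.frame chain, resno, resname, elety).
#' @export
selectAtoms <- function(model, sel, chain = NULL, restrict = NULL) {
  if (is(sel, "Selection")) sel <- list(sel)
  a <- model@atoms
  out <- lapply(sel, function(s) {
    chains <- if (!is.null(chain)) chain else
      names(model@roleMap)[model@roleMap == s@chainRole]
    if (!length(chains))
      stop("no chain with role '", s@chainRole, "' in model")
    want <- expandRanges(s@ranges)
    if (!is.null(restrict)) want <- intersect(want, restrict)
    rows <- do.call(rbind, lapply(sort(chains), function(ch) {
      sub <- a[a$chain == ch & a$resno %in% want & !a$het, , drop = FALSE]
      sub <- switch(s@atomFilter,
        CA = sub[sub$elety == "CA", , drop = FALSE],
        heavy = sub[toupper(sub$element) != "H", , drop = FALSE],
        all = a[a$chain == ch & a$resno %in% want, , drop = FALSE])
      missing <- setdiff(want, unique(sub$resno))
      if (length(missing))
        stop("missing residues for role ", s@chainRole, ", chain ", ch,
             " (", s@atomFilter, "): ",
             paste(missing, collapse = ", "), call. = FALSE)
      sub[order(sub$resno, sub$elety), , drop = FALSE]
    }))
    rows
  })
  rows <- do.call(rbind, out)
  list(coords = as.matrix(rows[, c("x", "y", "z")]),
       labels = rows[, c("chain", "resno", "resname", "elety")])
}

#' Residues resolved in every structure of a batch
#'
#' Used by the "intersect" selection mode: PCA residue subsets must be
#' resolved in all structures analysed together.
#'
#' @param models list of [StructureModel-class].
#' @param role chain role to inspect.
#' @return sorted integer vector of residue numbers present (with a CA atom)
#'   in every chain of that role in every model.
#' @export
commonResidues <- function(models, role) {
  sets <- lapply(models, function(m) {
    chains <- names(m@roleMap)[m@roleMap == role]
    a <- m@atoms
    Reduce(intersect, lapply(chains, function(ch)
      unique(a$resno[a$chain == ch & a$elety == "CA" & !a$het])))
  })
  sort(Reduce(intersect, sets))
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL block per frame.  Coordinates outside the fixed-width PDB
#' coordinate field (-999.999 to 9999.999) raise an error rather than being
#' truncated.  Round-trip contract: re-reading reproduces coordinates to
#' 3 decimals and labels exactly.
#'
#' @param traj a [Trajectory-class] (or a [StructureModel-class] for a
#'   single-model file).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(traj, path) {
  if (is(traj, "StructureModel"))
    traj <- new("Trajectory", topology = traj,
                xyz = matrix(as.vector(t(coords(traj))), nrow = 1L),
                times = 0, metadata = data.frame())
  if (!nFrames(traj)) stop("empty trajectory")
  if (max(traj@xyz) > 9999.999 || min(traj@xyz) < -999.999)
    stop("coordinate exceeds the fixed-width PDB field (-999.999..9999.999)")
  a <- traj@topology@atoms
  bio3d::write.pdb(file = path, xyz = traj@xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname,
                   chain = a$chain, elety = a$elety, elesy = a$element)
  invisible(path)
}

#' Write / read per-frame metadata as CSV
#'
#' Plain CSV with columns `frame`, `time_ns`, then one column per metadata
#' key.
#'
#' @param traj a [Trajectory-class].
#' @param path CSV path.
#' @return `writeFrameMetadata`: `path` invisibly; `readFrameMetadata`: a
#'   data.frame.
#' @export
writeFrameMetadata <- function(traj, path) {
  df <- data.frame(frame = seq_len(nFrames(traj)), time_ns = traj@times)
  if (nrow(traj@metadata)) df <- cbind(df, traj@metadata)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFrameMetadata
#' @export
readFrameMetadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a selection config
#'
#' YAML-style key-value file naming selections by role with range strings,
#' e.g. `gamma_core: {role: gamma, ranges: "1-26,228-272", atoms: CA}`.
#'
#' @param path config file path.
#' @return named list of [Selection-class] objects.
#' @export
readSelectionConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(s)
    Selection(s$role, s$ranges, if (is.null(s$atoms)) "CA" else s$atoms))
}
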