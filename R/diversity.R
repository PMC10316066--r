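#' Read a tree inventory from CSV
#'
#' Expects the header `plot_id,species,dbh_cm` with optional `x`, `y` and
#' `height_m` columns. Species labels are trimmed and lower-cased so
#' synonymous spellings collapse to one label.
#'
#' @param path CSV file path.
#' @return A data frame of tree records.
#' @export
read_inventory <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "species", "dbh_cm")
  if (!all(need %in% names(d)))
    stop("inventory CSV must have columns plot_id, species, dbh_cm")
  d$plot_id <- as.character(d$plot_id)
  d$species <- tolower(trimws(as.character(d$species)))
  if (any(!nzchar(d$species))) stop("empty species label in inventory")
  if (any(d$dbh_cm <= 0)) stop("dbh_cm must be positive")
  d
}

#' Filter trees by minimum stem diameter
#'
#' Keeps records with diameter at breast height at or above the census
#' threshold (inclusive). The standard forest census threshold of 5 cm is
#' the default.
#'
#' @param records data frame of tree records with a `dbh_cm` column.
#' @param min_dbh minimum DBH in cm (inclusive).
#' @return The filtered data frame; the number of removed records is
#'   reported via `message()`.
#' @export
filter_trees <- function(records, min_dbh = 5) {
  stopifnot(is.data.frame(records), "dbh_cm" %in% names(records))
  keep <- records$dbh_cm >= min_dbh
  if (any(!keep))
    message(sum(!keep), " tree(s) below ", min_dbh, " cm DBH removed")
  records[keep, , drop = FALSE]
}

# species abundance vector (counts) of one plot's records
.abundance <- function(records) {
  sp <- tolower(trimws(as.character(records$species)))
  table(sp[nzchar(sp)])
}

#' Shannon's H species diversity of a plot inventory
#'
#' H = -sum(p_i * log(p_i)) over species relative abundances p_i, natural
#' log by default. H is 0 for a monoculture and log(q) for q equally
#' abundant species.
#'
#' @param records data frame of tree records for one plot (columns
#'   `species`, `dbh_cm`).
#' @param base logarithm base (default `exp(1)`, the ecological convention).
#' @return Non-negative Shannon diversity.
#' @export
shannon_h <- function(records, base = exp(1)) {
  n <- .abundance(records)
  if (sum(n) < 1L) stop("empty inventory")
  p <- as.numeric(n) / sum(n)
  -sum(p * log(p, base = base))
}

#' Species richness of a plot inventory
#'
#' @inheritParams shannon_h
#' @return Count of distinct species labels (case-insensitive, trimmed).
#' @export
species_richness <- function(records) {
  n <- .abundance(records)
  if (sum(n) < 1L) stop("empty inventory")
  length(n)
}

#' Tree density of a plot (stems per plot)
#'
#' @inheritParams shannon_h
#' @return Number of tree records (0 for an empty inventory).
#' @export
tree_density <- function(records) {
  if (is.null(records)) return(0L)
  nrow(records)
}

#' Per-plot field diversity table
#'
#' Applies the DBH census filter once, then computes Shannon's H, species
#' richness and stem count for every plot in the inventory.
#'
#' @param inventory data frame of tree records (`plot_id`, `species`,
#'   `dbh_cm`).
#' @param min_dbh census threshold in cm (inclusive).
#' @param base logarithm base for Shannon's H.
#' @return Data frame with columns `plot_id`, `shannon_h`, `richness`,
#'   `n_trees`.
#' @export
diversity_table <- function(inventory, min_dbh = 5, base = exp(1)) {
  inv <- filter_trees(inventory, min_dbh)
  ids <- unique(as.character(inventory$plot_id))
  rows <- lapply(ids, function(id) {
    r <- inv[inv$plot_id == id, , drop = FALSE]
    if (nrow(r) == 0L)
      return(data.frame(plot_id = id, shannon_h = NA_real_,
                        richness = NA_integer_, n_trees = 0L))
    data.frame(plot_id = id, shannon_h = shannon_h(r, base = base),
               richness = species_richness(r), n_trees = tree_density(r))
  })
  do.call(rbind, rows)
}
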