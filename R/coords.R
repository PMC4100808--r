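# Circular rCRS coordinate arithmetic and control-region geometry.
# Coordinates throughout are 1-based, closed intervals on the 16,569-bp
# circular human mtDNA reference (rCRS, NC_012920); an interval with
# start > end crosses the origin.

#' rCRS genome length
#' @return Integer length of the rCRS mitochondrial genome (16,569 bp).
#' @export
#' @examples
#' rCRSLength()
rCRSLength <- function() 16569L

#' Default control-region fragment
#'
#' The 853-bp amplicon analysed by the pipeline: rCRS positions
#' 15978--16569 followed by 1--261, crossing the circular origin.
#'
#' @return Named integer vector with elements `start`, `end`,
#'   `genomeLength`.
#' @export
fragmentCoords <- function() {
  c(start = 15978L, end = 261L, genomeLength = 16569L)
}

#' Length of a closed interval on a circular genome
#'
#' @param start,end 1-based positions; `start > end` denotes an interval
#'   crossing the origin.
#' @param genomeLength Circular genome length in bp.
#' @return Integer interval length in bp, always in `[1, genomeLength]`.
#' @export
#' @examples
#' circularIntervalLength(15978, 261)  # the 853-bp control-region fragment
circularIntervalLength <- function(start, end, genomeLength = rCRSLength()) {
  start <- as.integer(start); end <- as.integer(end)
  genomeLength <- as.integer(genomeLength)
  if (any(is.na(start)) || any(is.na(end)) ||
      any(start < 1L) || any(start > genomeLength) ||
      any(end < 1L) || any(end > genomeLength)) {
    stop2("coordinate error: positions must lie in [1, ", genomeLength, "]",
          class = "mitoHet_coordinate_error")
  }
  ifelse(start <= end,
         end - start + 1L,
         (genomeLength - start + 1L) + end)
}

#' Enumerate the positions of a circular interval
#'
#' Positions are enumerated explicitly along the arc (not via modular
#' offsets), so region boundaries remain auditable.
#'
#' @inheritParams circularIntervalLength
#' @return Ordered integer vector of positions.
#' @export
#' @examples
#' length(fragmentPositions())  # 853
fragmentPositions <- function(start = 15978L, end = 261L,
                              genomeLength = rCRSLength()) {
  n <- circularIntervalLength(start, end, genomeLength)  # validates
  start <- as.integer(start); end <- as.integer(end)
  if (start <= end) seq.int(start, end)
  else c(seq.int(start, as.integer(genomeLength)), seq.int(1L, end))
}

#' Default hypervariable-region map
#'
#' HV1 (15978--16364), the intermediate region (16365--72, crossing the
#' origin) and HV2 (73--261).  The three intervals partition the fragment.
#'
#' @return `data.frame` with columns `region`, `start`, `end`.
#' @export
defaultRegionMap <- function() {
  data.frame(
    region = c("HV1", "INTERMEDIATE", "HV2"),
    start  = c(15978L, 16365L, 73L),
    end    = c(16364L, 72L, 261L),
    stringsAsFactors = FALSE
  )
}

validateRegionMap <- function(map, fragment = fragmentPositions()) {
  stopifnot(is.data.frame(map),
            all(c("region", "start", "end") %in% names(map)))
  posList <- regionPositions(map)
  all_pos <- unlist(posList, use.names = FALSE)
  if (anyDuplicated(all_pos))
    stop2("region map error: regions overlap",
          class = "mitoHet_coordinate_error")
  if (!setequal(all_pos, fragment))
    stop2("region map error: regions do not partition the fragment",
          class = "mitoHet_coordinate_error")
  invisible(map)
}

# list: region name -> integer positions (explicit arc enumeration)
regionPositions <- function(map = defaultRegionMap()) {
  out <- lapply(seq_len(nrow(map)), function(i)
    fragmentPositions(map$start[i], map$end[i]))
  names(out) <- map$region
  out
}

#' Assign fragment positions to control-region segments
#'
#' @param pos Integer vector of rCRS positions within the fragment.
#' @param map Region map (`data.frame` as [defaultRegionMap()]).
#' @return Character vector of region labels, one per position.
#' @export
#' @examples
#' assignRegion(c(16100, 50, 100))
assignRegion <- function(pos, map = defaultRegionMap()) {
  pos <- as.integer(pos)
  posList <- regionPositions(map)
  lab <- rep(NA_character_, length(pos))
  for (r in names(posList)) lab[pos %in% posList[[r]]] <- r
  if (anyNA(lab))
    stop2("out-of-fragment position(s): ",
          paste(pos[is.na(lab)], collapse = ", "),
          class = "mitoHet_coordinate_error")
  lab
}

#' Region sizes in bp
#'
#' @param map Region map.
#' @return Named integer vector of region lengths; sizes sum to the
#'   fragment length.
#' @export
regionSizes <- function(map = defaultRegionMap()) {
  vapply(regionPositions(map), length, integer(1))
}

#' Read / write a region map
#'
#' Tab-separated, three columns `region`, `start`, `end`, 1-based closed
#' rCRS coordinates.
#'
#' @param path File path.
#' @param map Region map `data.frame`.
#' @return `readRegionMap` returns the validated map; `writeRegionMap`
#'   returns `path` invisibly.
#' @export
readRegionMap <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  validateRegionMap(map)
  map
}

#' @rdname readRegionMap
#' @export
writeRegionMap <- function(map, path) {
  validateRegionMap(map)
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# classed condition helper
stop2 <- function(..., class, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
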