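six_column_world <- function() {
  df <- data.frame(
    identifier = c("g1", "g2"),
    logFC_d1 = c(0.5, -0.5), logFC_d2 = c(1, -1), logFC_d5 = c(0, 0.2),
    P_d1 = c(0.01, 0.5), P_d2 = c(0.04, 0.2), P_d5 = c(0.5, 0.01),
    stringsAsFactors = FALSE)
  tab <- as_measurement_table(df, id_column = "identifier", syscode = "L")
  g <- color_gradient(c(-1, 0, 1), c("blue", "white", "red"))
  spec <- visualization_spec(list(
    logFC_d1 = g, logFC_d2 = g, logFC_d5 = g,
    P_d1 = list(color_rule("[P_d1] <= 0.05", "green")),
    P_d2 = list(color_rule("[P_d2] <= 0.05", "green")),
    P_d5 = list(color_rule("[P_d5] <= 0.05", "green"))))
  doc <- create_pathway("overlay", "Mus musculus")
  mapped <- add_data_node(doc, "g1", xref = xref("g1", "L"), cx = 60, cy = 30)
  unmapped <- add_data_node(doc, "absent", xref = xref("nope", "L"), cx = 60, cy = 80)
  lk <- link_to_pathway(tab, doc, NULL)
  list(doc = doc, tab = tab, spec = spec, lk = lk,
       mapped = mapped, unmapped = unmapped)
}

node_stripes <- function(rendered, node_id) {
  h <- rendered$hit_regions
  h <- h[h$element_id == node_id, ]
  r <- svg_rects(rendered$svg)
  r <- r[r$fill != "none" & r$y == h$y & r$height == h$height &
           r$x >= h$x & r$x + r$width <= h$x + h$width, ]
  r[order(r$x), ]
}

test_that("a six-column spec paints six exact stripes per mapped node", {
  w <- six_column_world()
  rendered <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  s <- node_stripes(rendered, w$mapped)
  expect_equal(nrow(s), 6L)
  h <- rendered$hit_regions[rendered$hit_regions$element_id == w$mapped, ]
  expect_equal(sum(s$width), h$width)           # stripes tile the node exactly
  expect_equal(s$x[-1], head(s$x + s$width, -1))  # no gaps, no overlap
  # gradient stripes and the day-1 significance rule colour
  expect_equal(s$fill[[2]], "#FF0000")  # logFC_d2 = 1 -> red anchor
  expect_equal(s$fill[[4]], "#00FF00")  # P_d1 = 0.01 -> green rule
  expect_equal(s$fill[[6]], "#FFFFFF")  # P_d5 = 0.5 -> white otherwise
})

test_that("unmapped nodes are solid light grey and single entries span the node", {
  w <- six_column_world()
  rendered <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  s_un <- node_stripes(rendered, w$unmapped)
  expect_equal(nrow(s_un), 1L)
  expect_equal(s_un$fill, "#D3D3D3")
  one <- visualization_spec(list(logFC_d1 = w$spec$entries$logFC_d1))
  r1 <- render_pathway(w$doc, w$lk, w$tab, one)
  s1 <- node_stripes(r1, w$mapped)
  h <- r1$hit_regions[r1$hit_regions$element_id == w$mapped, ]
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$width, h$width)
})

test_that("every data node gets exactly one in-canvas hit region", {
  w <- six_column_world()
  rendered <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  expect_equal(sort(rendered$hit_regions$element_id),
               sort(element_ids(w$doc, "DataNode")))
  with(rendered$hit_regions, {
    expect_true(all(x >= 0 & y >= 0))
    expect_true(all(x + width <= rendered$width_px))
    expect_true(all(y + height <= rendered$height_px))
  })
})

test_that("rendering is deterministic and raster pixels match stripe colours", {
  w <- six_column_world()
  r1 <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  r2 <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  expect_identical(r1$svg, r2$svg)
  expect_identical(r1$raster, r2$raster)
  s <- node_stripes(r1, w$mapped)
  mid_y <- s$y[[1]] + s$height[[1]] / 2
  for (j in seq_len(nrow(s))) {
    px <- r1$raster[round(mid_y), round(s$x[[j]] + s$width[[j]] / 2), ]
    expect_equal(toupper(grDevices::rgb(px[1], px[2], px[3])), toupper(s$fill[[j]]))
  }
})

test_that("a spec referencing a column the table lacks is rejected", {
  w <- six_column_world()
  bad <- visualization_spec(list(absent = color_gradient(c(0, 1), c("white", "red"))))
  expect_error(render_pathway(w$doc, w$lk, w$tab, bad), "absent column")
})

test_that("the legend shows one block per entry with anchors labelled", {
  w <- six_column_world()
  lg <- make_legend(w$spec)
  expect_equal(lg$n_blocks, 6L)
  expect_match(lg$svg, ">-1</text>", fixed = TRUE)
  expect_match(lg$svg, ">0</text>", fixed = TRUE)
  expect_match(lg$svg, ">1</text>", fixed = TRUE)
  expect_match(lg$svg, "P_d1] &lt;= 0.05")
  empty <- make_legend(visualization_spec(list()))
  expect_equal(empty$n_blocks, 0L)
})

test_that("images write to SVG and PNG", {
  w <- six_column_world()
  rendered <- render_pathway(w$doc, w$lk, w$tab, w$spec)
  svg_path <- withr::local_tempfile(fileext = ".svg")
  png_path <- withr::local_tempfile(fileext = ".png")
  write_image(rendered, svg_path)
  write_image(rendered, png_path)
  expect_true(file.size(svg_path) > 0)
  back <- png::readPNG(png_path)
  expect_equal(dim(back)[1:2], c(rendered$height_px, rendered$width_px))
  expect_error(write_image(rendered, "x.gif"), "unsupported image extension")
})
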