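# Default geometry / analysis configuration for gammaQC.
#
# Everything here mirrors the built-in defaults; copy and edit for your
# site. Sphere and rod physical sizes and ring radii are DATASHEET DEFAULTS
# for the standard commercial ACR SPECT phantom -- confirm them against the
# datasheet of the phantom you actually scan.

bar_templates:
  bar1:
    bar_widths_mm: [3.5, 3.0, 2.5, 2.0]
    roi_offset_mm: [134, 104]
    roi_diameter_mm: 132
    thresholds: [0.15, 0.1]
  bar2:
    bar_widths_mm: [4.0, 3.5, 3.2, 2.5]
    roi_offset_mm: [134, 104]
    roi_diameter_mm: 132
    thresholds: [0.15, 0.1]
  bar3:
    bar_widths_mm: [6.4, 4.8, 4.0, 3.2]
    roi_offset_mm: [106, 106]
    roi_diameter_mm: 132
    thresholds: [0.5, 0.25]

acr:
  interior_radius_mm: 108
  background_roi_diameter_mm: 69.2
  sphere_diameters_mm: [31.8, 25.4, 19.1, 15.9, 12.7, 9.5]
  sphere_ring_radius_mm: 54
  sphere_roi_scale: 1.0
  rod_sector_diameters_mm: [12.7, 11.1, 9.5, 7.9, 6.4, 4.8]
  rod_line_length_mm: 72
  rod_row_radius_mm: 74
  uniformity_roi_diameter_mm: 50
  cnr_threshold: 3
  modulation_thresholds: [0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5]
  rod_aggregate_slices: 10

detection:
  threshold_fraction: 0.10
  kernel_px: 3
  blur_sigma_px: 1
  min_area_mm2: 2000

# DICOM tags used to assign incoming images to a device; site policy, not
# fixed by the software. Keys are descriptive, values are group,element.
device_tags:
  device: "0008,1010"    # StationName
  phantom: "0008,103E"   # SeriesDescription
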