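year,exporter_iso3,importer_iso3,taxon_name,production_method,is_reexport,tonnes
2000,CAN,USA,Gadus morhua,capture,FALSE,10
2000,USA,CAN,Gadus morhua,capture,FALSE,5
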