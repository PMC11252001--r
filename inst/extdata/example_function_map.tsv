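genus	function
genus_001	fermentation
genus_001	chemoheterotrophy
genus_002	chemoheterotrophy
genus_003	nitrate_reduction
genus_004	methanogenesis
genus_005	aerobic_chemoheterotrophy
genus_006	fermentation
genus_007	nitrate_reduction
genus_008	iron_respiration
genus_009	chemoheterotrophy
genus_010	fermentation
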