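>synthetic_pasb_query (stand-in, 4 substitutions: V2I R7E N78T Q79R)
YVSNRTRARPEPHSEHCAETYACHLTKYENDQKPLNLVYIGKLCKMFRCIGGKQLDPASTRCDINVSNPVLAVEVPLNQLIAGRDTVLLSRLVHYDGTDIIVVKHMDDTLIN
>synthetic_pasb_template (stand-in)
YISNRTEARPEPHSEHCAETYACHLTKYENDQKPLNLVYIGKLCKMFRCIGGKQLDPASTRCDINVSNPVLAVEVPLTRLIAGRDTVLLSRLVHYDGTDIIVVKHMDDTLIN
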